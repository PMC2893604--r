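#' Assemble a labeled cleavage-site dataset
#'
#' Positives are the annotated P1 positions; negatives are drawn from Asp
#' positions in the same proteins that are not annotated as cut sites --
#' mirroring the design of curated caspase training sets, where every
#' negative also carries Asp at P1 so that the P1 slot itself is
#' uninformative. Windows are extracted with `policy = "skip"` (sites whose
#' window overruns a terminus are dropped) and duplicate windows are
#' removed; a window occurring with both labels keeps only its positive
#' copy.
#'
#' @param proteins A [protein_records()] data frame.
#' @param positive_sites Named list mapping protein id to positive P1
#'   positions.
#' @param geometry A [window_geometry()].
#' @param negatives `"balanced"` samples as many negatives as there are
#'   positive windows, uniformly over eligible Asp positions;
#'   `"all"` keeps every eligible negative.
#' @param negative_sites Optional named list of negative P1 positions,
#'   overriding sampling.
#' @param seed Seed for negative sampling (balanced mode).
#' @param p1_motif Required P1 residue for annotated positives (`NULL`
#'   disables the check).
#' @param on_p1_mismatch What to do with a positive whose P1 residue does
#'   not match `p1_motif`: drop it with a warning (default), keep it, or
#'   error.
#' @return A `labeled_dataset`: list with the feature matrix `x` (one-hot
#'   rows), labels `y` in -1/+1, a `sites` data frame
#'   (protein_id, p1, window, label), the `geometry`, and a `provenance`
#'   string.
#' @export
build_dataset <- function(proteins, positive_sites, geometry,
                          negatives = c("balanced", "all"),
                          negative_sites = NULL, seed = 1L,
                          p1_motif = "D",
                          on_p1_mismatch = c("drop", "keep", "error")) {
  negatives <- match.arg(negatives)
  on_p1_mismatch <- match.arg(on_p1_mismatch)
  stopifnot(inherits(proteins, "protein_records"))
  seqs <- stats::setNames(proteins$sequence, proteins$id)

  pos <- .site_table(positive_sites, seqs, what = "positive")
  if (!is.null(p1_motif)) {
    p1res <- substring(seqs[pos$protein_id], pos$p1, pos$p1)
    bad <- p1res != p1_motif
    if (any(bad)) {
      msg <- sprintf("%d positive site(s) lack %s at P1", sum(bad), p1_motif)
      if (on_p1_mismatch == "error") stop(msg)
      if (on_p1_mismatch == "drop") {
        warning(msg, "; dropped")
        pos <- pos[!bad, , drop = FALSE]
      } else {
        warning(msg, "; kept")
      }
    }
  }

  if (is.null(negative_sites)) {
    neg <- .eligible_negatives(seqs, positive_sites, p1_motif %||% "D")
  } else {
    neg <- .site_table(negative_sites, seqs, what = "negative")
  }

  pos$window <- extract_window_at(seqs, pos, geometry)
  neg$window <- extract_window_at(seqs, neg, geometry)
  n_pos_dropped <- sum(is.na(pos$window))
  if (n_pos_dropped > 0L) {
    warning(n_pos_dropped, " positive site(s) dropped: window overruns a terminus")
  }
  pos <- pos[!is.na(pos$window), , drop = FALSE]
  neg <- neg[!is.na(neg$window), , drop = FALSE]
  pos <- pos[!duplicated(pos$window), , drop = FALSE]
  neg <- neg[!duplicated(neg$window), , drop = FALSE]
  clash <- neg$window %in% pos$window
  if (any(clash)) {
    warning(sum(clash), " negative window(s) identical to a positive window; dropped")
    neg <- neg[!clash, , drop = FALSE]
  }

  if (is.null(negative_sites) && negatives == "balanced") {
    if (nrow(neg) > nrow(pos)) {
      keep <- .with_seed(seed, sample.int(nrow(neg), nrow(pos)))
      neg <- neg[sort(keep), , drop = FALSE]
    } else if (nrow(neg) < nrow(pos)) {
      warning("only ", nrow(neg), " eligible negatives for ", nrow(pos),
              " positives; dataset is unbalanced")
    }
  }

  sites <- rbind(
    cbind(pos, label = rep(1L, nrow(pos))),
    cbind(neg, label = rep(-1L, nrow(neg)))
  )
  rownames(sites) <- NULL
  x <- encode_windows(sites$window, geometry)
  structure(
    list(
      x = x, y = sites$label, sites = sites, geometry = geometry,
      provenance = sprintf("%d proteins; %d positives, %d negatives (%s)",
                           nrow(proteins), nrow(pos), nrow(neg), negatives)
    ),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled cleavage-site dataset:", nrow(x$x), "sites,",
      format(x$geometry), "\n  ", x$provenance, "\n")
  invisible(x)
}

# Flatten a named position list against the sequences, range-checking.
.site_table <- function(site_list, seqs, what) {
  if (length(site_list) == 0L) {
    return(data.frame(protein_id = character(0), p1 = integer(0)))
  }
  unknown <- setdiff(names(site_list), names(seqs))
  if (length(unknown)) {
    stop(what, " sites reference unknown protein(s): ", paste(unknown, collapse = ", "))
  }
  out <- data.frame(
    protein_id = rep(names(site_list), lengths(site_list)),
    p1 = as.integer(unlist(site_list, use.names = FALSE))
  )
  n <- nchar(seqs[out$protein_id])
  if (any(out$p1 < 1L | out$p1 > n)) {
    i <- which(out$p1 < 1L | out$p1 > n)[1]
    stop(what, " site out of range: ", out$protein_id[i], " position ", out$p1[i])
  }
  out
}

.eligible_negatives <- function(seqs, positive_sites, p1_motif) {
  rows <- lapply(names(seqs), function(id) {
    d <- scan_candidates(seqs[[id]], motif = p1_motif)
    d <- setdiff(d, positive_sites[[id]])
    if (length(d)) data.frame(protein_id = id, p1 = d) else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(protein_id = character(0), p1 = integer(0)) else out
}

# Vectorised window extraction over a site table (skip policy).
extract_window_at <- function(seqs, sites, geometry, policy = "skip") {
  if (nrow(sites) == 0L) return(character(0))
  vapply(seq_len(nrow(sites)), function(i) {
    extract_window(seqs[[sites$protein_id[i]]], sites$p1[i], geometry, policy)
  }, character(1))
}

#' Generate a synthetic training corpus with planted caspase motifs
#'
#' Proteins are i.i.d. uniform over the 20 residues; positive sites are
#' planted by overwriting a P4-P1 motif drawn from the three canonical
#' caspase recognition classes -- `DEXD` (caspases 2/3/7), `[WL]EHD`
#' (caspases 1/4/5/13) and `[ILV]E[HT]D` (caspases 6/8/9/10) -- so every
#' planted site ends in Asp at P1. The residue after the cut (P1') is
#' enriched for small residues (G/A/S) at a configurable rate, giving
#' classifiers a learnable signal beyond the P4-P1 motif. Unplanted Asp
#' positions serve as negatives. Deterministic given `seed`.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Inclusive range of protein lengths, sampled
#'   uniformly.
#' @param planting_rate Expected planted sites per protein (Poisson).
#' @param motif_weights Sampling weights of the three motif classes, in the
#'   order DEXD, \[WL\]EHD, \[ILV\]E\[HT\]D.
#' @param p1prime_small_rate Probability that the P1' residue is drawn from
#'   G/A/S rather than uniformly.
#' @param seed Integer seed; the global RNG state is restored on exit.
#' @return List with `proteins` ([protein_records()]), `positive_sites`
#'   (named list of planted P1 positions) and `motif_classes` (factor of
#'   the class planted at each site, in site order).
#' @export
generate_synthetic_corpus <- function(n_proteins = 100,
                                      length_range = c(60, 200),
                                      planting_rate = 1.25,
                                      motif_weights = c(0.5, 0.25, 0.25),
                                      p1prime_small_rate = 0.5,
                                      seed = 1L) {
  stopifnot(n_proteins >= 1, length(length_range) == 2L,
            length_range[1] >= 12, length_range[1] <= length_range[2],
            planting_rate >= 0, length(motif_weights) == 3L,
            all(motif_weights >= 0), sum(motif_weights) > 0,
            p1prime_small_rate >= 0, p1prime_small_rate <= 1)
  aa <- aa_residues()
  classes <- c("DEXD", "[WL]EHD", "[ILV]E[HT]D")
  .with_seed(seed, {
    ids <- sprintf("synth%04d", seq_len(n_proteins))
    seqs <- character(n_proteins)
    site_list <- vector("list", n_proteins)
    class_list <- vector("list", n_proteins)
    for (i in seq_len(n_proteins)) {
      L <- sample(length_range[1]:length_range[2], 1L)
      s <- sample(aa, L, replace = TRUE)
      k <- stats::rpois(1L, planting_rate)
      p1s <- integer(0)
      tries <- 0L
      while (length(p1s) < k && tries < 100L) {
        cand <- sample(5:(L - 1L), 1L)
        # footprint P4..P1' must not overlap an existing plant's footprint
        if (all(abs(cand - p1s) > 5L)) p1s <- c(p1s, cand)
        tries <- tries + 1L
      }
      p1s <- sort(p1s)
      cls <- character(length(p1s))
      for (j in seq_along(p1s)) {
        p1 <- p1s[j]
        ci <- sample.int(3L, 1L, prob = motif_weights)
        cls[j] <- classes[ci]
        s[(p1 - 3L):p1] <- switch(ci,
          c("D", "E", sample(aa, 1L), "D"),
          c(sample(c("W", "L"), 1L), "E", "H", "D"),
          c(sample(c("I", "L", "V"), 1L), "E", sample(c("H", "T"), 1L), "D")
        )
        s[p1 + 1L] <- if (stats::runif(1) < p1prime_small_rate) {
          sample(c("G", "A", "S"), 1L)
        } else {
          sample(aa, 1L)
        }
      }
      seqs[i] <- paste(s, collapse = "")
      site_list[[i]] <- p1s
      class_list[[i]] <- cls
    }
    names(site_list) <- ids
    list(
      proteins = protein_records(ids, seqs),
      positive_sites = site_list[lengths(site_list) > 0L],
      motif_classes = factor(unlist(class_list, use.names = FALSE), levels = classes)
    )
  })
}

#' Build aligned datasets at several window geometries
#'
#' Classifiers with different windows (e.g. the SVM's 6-4 and the random
#' forest's 12-12) can only be combined site by site -- in a Vote ensemble
#' or a per-site comparison -- when they are trained and evaluated on the
#' same sites in the same order. This builds one dataset per geometry over
#' a common site set: site selection, terminal-window skipping,
#' deduplication and balanced negative sampling are all performed once at
#' the enclosing (maximal) geometry, then each requested geometry encodes
#' its own narrower window around the identical sites.
#'
#' @inheritParams build_dataset
#' @param geometries Named list of [window_geometry()] objects.
#' @return Named list of `labeled_dataset`s whose `sites` tables are
#'   identical row for row.
#' @export
build_aligned_datasets <- function(proteins, positive_sites, geometries,
                                   negatives = c("balanced", "all"),
                                   seed = 1L, p1_motif = "D") {
  stopifnot(length(geometries) >= 1L, !is.null(names(geometries)))
  gmax <- window_geometry(
    max(vapply(geometries, `[[`, 0L, "n_left")),
    max(vapply(geometries, `[[`, 0L, "n_right"))
  )
  base <- build_dataset(proteins, positive_sites, gmax, negatives = negatives,
                        seed = seed, p1_motif = p1_motif)
  seqs <- stats::setNames(proteins$sequence, proteins$id)
  lapply(geometries, function(g) {
    w <- extract_window_at(seqs, base$sites, g)
    sites <- base$sites
    sites$window <- w
    structure(
      list(x = encode_windows(w, g), y = base$y, sites = sites, geometry = g,
           provenance = paste0(base$provenance, " [aligned at ", format(gmax), "]")),
      class = "labeled_dataset"
    )
  })
}

#' Stratified train/test split of a labeled dataset
#'
#' @param ds A `labeled_dataset`.
#' @param fraction Proportion assigned to the training part, stratified by
#'   label; each class must have at least 2 members.
#' @param seed Integer seed; the global RNG state is restored on exit.
#' @return List of two `labeled_dataset`s, `train` and `test`; every site
#'   appears in exactly one part.
#' @export
split_dataset <- function(ds, fraction = 2 / 3, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"), fraction > 0, fraction < 1)
  if (min(table(ds$y)) < 2L) stop("each class needs at least 2 members to split")
  idx <- .with_seed(seed, {
    unlist(lapply(split(seq_along(ds$y), ds$y), function(i) {
      sample(i, round(fraction * length(i)))
    }), use.names = FALSE)
  })
  list(train = .subset_dataset(ds, sort(idx)),
       test = .subset_dataset(ds, setdiff(seq_along(ds$y), idx)))
}

.subset_dataset <- function(ds, idx) {
  structure(
    list(x = ds$x[idx, , drop = FALSE], y = ds$y[idx],
         sites = ds$sites[idx, , drop = FALSE], geometry = ds$geometry,
         provenance = paste0(ds$provenance, " [subset n=", length(idx), "]")),
    class = "labeled_dataset"
  )
}

# Run `expr` under a temporary seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
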