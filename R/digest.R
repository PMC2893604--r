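#' Digestion options
#'
#' The three output modes mirror the tool's cleavage-product conventions:
#' `"single_site"` cuts each protein at one predicted site at a time (the
#' biologically motivated default -- a substrate molecule is typically cut
#' at a single site), `"all_sites"` cuts at every predicted site
#' simultaneously, and `"all_combinations"` emits the products of every
#' subset of the predicted sites.
#'
#' @param mode One of `"single_site"`, `"all_sites"`,
#'   `"all_combinations"`.
#' @param include_full_sequence Also emit the intact sequence.
#' @param motif P1-anchored motif pattern(s) to restrict candidate sites
#'   (see [motif_to_regex()]); default Asp at P1. `NULL` scans every
#'   position.
#' @param min_fragment_length Fragments shorter than this are dropped
#'   (very short fragments are useless for MS identification).
#' @return A `digest_options` list.
#' @export
digest_options <- function(mode = c("single_site", "all_sites", "all_combinations"),
                           include_full_sequence = FALSE, motif = "D",
                           min_fragment_length = 1L) {
  mode <- match.arg(mode)
  stopifnot(min_fragment_length >= 1L)
  structure(list(mode = mode, include_full_sequence = include_full_sequence,
                 motif = motif, min_fragment_length = as.integer(min_fragment_length)),
            class = "digest_options")
}

#' Predict cut sites in one protein
#'
#' Scans the candidate positions selected by the motif and classifies each
#' with the given classifier (or Vote ensemble); terminal windows are
#' zero-padded so near-terminal sites are still evaluated.
#'
#' @param protein Single-row [protein_records()] or sequence string.
#' @param clf A trained `site_classifier` or [vote_classifier()].
#' @param opts A [digest_options()] (supplies the motif).
#' @param policy Terminal-window policy passed to [classify_sites()].
#' @return Sorted integer vector of predicted P1 positions.
#' @export
predict_sites <- function(protein, clf, opts = digest_options(), policy = "pad") {
  sequence <- .as_sequence(protein)
  cand <- scan_candidates(sequence, motif = opts$motif)
  if (length(cand) == 0L) return(integer(0))
  lab <- classify_sites(clf, sequence, cand, policy = policy)
  lab[is.na(lab)] <- -1L
  sort(cand[lab == 1L])
}

#' Use a known cut-site list instead of prediction
#'
#' Proteins with user-given cleavage sites bypass the classifier entirely;
#' products are derived from the given P1 positions only.
#'
#' @param protein Single-row [protein_records()] or sequence string; used
#'   for range validation.
#' @param known Integer vector of known P1 positions (one entry of
#'   [read_known_sites()]).
#' @param protein_id Identifier used in error messages.
#' @return Sorted integer vector of P1 positions.
#' @export
apply_known_sites <- function(protein, known, protein_id = "?") {
  sequence <- .as_sequence(protein)
  if (inherits(protein, "protein_records")) protein_id <- protein$id
  known <- as.integer(known)
  n <- nchar(sequence)
  bad <- known < 1L | known > n
  if (any(bad)) {
    stop("known cut site out of range for protein '", protein_id, "': position ",
         known[bad][1], " (sequence length ", n, ")")
  }
  sort(unique(known))
}

#' Cut a protein into cleavage products
#'
#' Cuts fall immediately C-terminal to each P1 position. Modes (for `k`
#' cuts): `single_site` yields the N- and C-terminal pair for each cut
#' taken alone; `all_sites` the `k + 1` consecutive fragments of cutting
#' everywhere at once; `all_combinations` every fragment arising from any
#' subset of the cuts -- equivalently every span whose boundaries are each
#' a terminus or a cut, `(k+1)(k+2)/2` spans before deduplication
#' (including the intact sequence, from the empty subset). Identical
#' spans are emitted once; provenance (parent, span, cuts used, P4-P1
#' motif context at each used cut) is kept per fragment.
#'
#' @param protein Single-row [protein_records()] or sequence string.
#' @param cuts Integer vector of P1 positions (validated, deduplicated,
#'   sorted here).
#' @param mode Digestion mode, see [digest_options()].
#' @param include_full_sequence Append the intact span if not already
#'   present.
#' @param min_fragment_length Drop shorter fragments.
#' @param parent_id Identifier recorded in the products (taken from the
#'   record when given one).
#' @return A `cleavage_products` data frame: `parent_id`, `start`, `end`,
#'   `sequence`, `cuts_used` (comma-joined P1 positions bounding the
#'   fragment), `motif_context` (semicolon-joined P4-P1 context at each
#'   used cut, `-`-padded at the N terminus).
#' @export
fragment_protein <- function(protein, cuts, mode = "single_site",
                             include_full_sequence = FALSE,
                             min_fragment_length = 1L, parent_id = "protein") {
  sequence <- .as_sequence(protein)
  if (inherits(protein, "protein_records")) parent_id <- protein$id
  L <- nchar(sequence)
  cuts <- sort(unique(as.integer(cuts)))
  if (any(cuts < 1L | cuts > L)) stop("cut position out of range for ", parent_id)
  inner <- cuts[cuts < L] # a cut after the last residue produces no new boundary

  spans <- switch(mode,
    single_site = {
      # a cut at p = L has an empty C-terminal product; only the left
      # fragment (the intact sequence) is emitted for it
      rbind(
        matrix(c(rep(1L, length(cuts)), cuts), ncol = 2),
        matrix(c(inner + 1L, rep(L, length(inner))), ncol = 2)
      )
    },
    all_sites = {
      b <- c(0L, inner, L)
      cbind(b[-length(b)] + 1L, b[-1])
    },
    all_combinations = {
      starts <- c(1L, inner + 1L)
      ends <- c(inner, L)
      g <- expand.grid(start = starts, end = ends)
      as.matrix(g[g$start <= g$end, , drop = FALSE])
    },
    stop("unknown digestion mode: ", mode)
  )
  if (include_full_sequence) spans <- rbind(spans, c(1L, L))
  if (nrow(spans)) {
    spans <- spans[!duplicated(spans[, 1] * (L + 1) + spans[, 2]), , drop = FALSE]
    spans <- spans[spans[, 2] - spans[, 1] + 1L >= min_fragment_length, , drop = FALSE]
    spans <- spans[order(spans[, 1], spans[, 2]), , drop = FALSE]
  }
  start <- as.integer(spans[, 1])
  end <- as.integer(spans[, 2])
  if (length(start) == 0L) {
    out <- data.frame(parent_id = character(0), start = integer(0), end = integer(0),
                      sequence = character(0), cuts_used = character(0),
                      motif_context = character(0), stringsAsFactors = FALSE)
    class(out) <- c("cleavage_products", "protein_records", "data.frame")
    return(out)
  }
  cut_ctx <- vapply(seq_along(start), function(i) {
    paste(intersect(cuts, c(start[i] - 1L, end[i])), collapse = ",")
  }, character(1))
  motif_ctx <- vapply(cut_ctx, function(cc) {
    if (!nzchar(cc)) return("")
    ps <- as.integer(strsplit(cc, ",", fixed = TRUE)[[1]])
    paste(vapply(ps, function(p) {
      paste0(strrep("-", max(0L, 4L - p)), substr(sequence, max(1L, p - 3L), p))
    }, character(1)), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  out <- data.frame(
    parent_id = rep(parent_id, length(start)),
    start = start, end = end,
    sequence = substring(sequence, start, end),
    cuts_used = cut_ctx, motif_context = motif_ctx,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cleavage_products", "protein_records", "data.frame")
  out
}

#' Digest a proteome into a cleavage-product FASTA database
#'
#' Streams over the input proteins: for each, cut sites are predicted with
#' the classifier (or taken from the known-sites list, which bypasses
#' prediction for that protein entirely), the protein is fragmented
#' according to the digestion mode, and products are appended to the
#' output FASTA with provenance headers. Memory use is bounded by one
#' protein's products, not by the output database.
#'
#' @param input Path to a FASTA file or a [protein_records()] data frame.
#' @param clf A trained `site_classifier` or [vote_classifier()].
#' @param output Path for the product FASTA; `NULL` collects products in
#'   memory and returns them in the summary's `products` element.
#' @param opts A [digest_options()].
#' @param known_sites Optional named list of known P1 positions (see
#'   [read_known_sites()]); listed proteins never reach the classifier.
#' @param lenient Log and skip per-protein failures instead of stopping.
#' @param relaxed Passed to [read_fasta()] when `input` is a path.
#' @return A `digest_summary`: proteins processed, proteins with at least
#'   one cut, percent cut, total cuts, mean cuts per cut protein, fragments
#'   written, failures skipped (and `products` when `output` is `NULL`).
#' @export
digest_proteome <- function(input, clf, output = NULL, opts = digest_options(),
                            known_sites = NULL, lenient = FALSE, relaxed = FALSE) {
  proteins <- if (inherits(input, "protein_records")) input else read_fasta(input, relaxed = relaxed)
  stopifnot(inherits(opts, "digest_options"))
  if (!is.null(output)) {
    con <- file(output, open = "wt")
    on.exit(close(con))
  }
  collected <- if (is.null(output)) vector("list", nrow(proteins)) else NULL
  n_cut <- 0L
  total_cuts <- 0L
  n_frag <- 0L
  n_skipped <- 0L
  for (i in seq_len(nrow(proteins))) {
    rec <- proteins[i, , drop = FALSE]
    class(rec) <- class(proteins)
    res <- tryCatch({
      cuts <- if (!is.null(known_sites) && rec$id %in% names(known_sites)) {
        apply_known_sites(rec, known_sites[[rec$id]])
      } else {
        predict_sites(rec, clf, opts)
      }
      frags <- fragment_protein(rec, cuts, mode = opts$mode,
                                include_full_sequence = opts$include_full_sequence,
                                min_fragment_length = opts$min_fragment_length)
      list(cuts = cuts, frags = frags)
    }, error = function(e) {
      if (!lenient) stop(e)
      warning("skipping protein '", rec$id, "': ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (length(res$cuts)) {
      n_cut <- n_cut + 1L
      total_cuts <- total_cuts + length(res$cuts)
    }
    n_frag <- n_frag + nrow(res$frags)
    if (!is.null(output)) {
      .write_fasta_con(con, fasta_headers(res$frags), res$frags$sequence)
    } else {
      collected[[i]] <- res$frags
    }
  }
  n_done <- nrow(proteins) - n_skipped
  out <- structure(
    list(
      n_proteins = n_done,
      n_cut_proteins = n_cut,
      pct_cut_proteins = if (n_done > 0) 100 * n_cut / n_done else 0,
      total_cuts = total_cuts,
      mean_cuts_per_cut_protein = if (n_cut > 0) total_cuts / n_cut else NA_real_,
      n_fragments = n_frag,
      n_skipped = n_skipped,
      mode = opts$mode
    ),
    class = "digest_summary"
  )
  if (is.null(output)) {
    prods <- do.call(rbind, collected)
    if (is.null(prods)) prods <- fragment_protein("A", integer(0))[0, ]
    class(prods) <- c("cleavage_products", "protein_records", "data.frame")
    out$products <- prods
  }
  out
}

#' @export
print.digest_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Digestion summary (%s mode):\n",
           "  proteins processed:          %d\n",
           "  proteins with >= 1 cut:      %d (%.1f%%)\n",
           "  predicted cuts total:        %d\n",
           "  mean cuts per cut protein:   %s\n",
           "  fragments written:           %d\n",
           "  proteins skipped:            %d\n"),
    x$mode, x$n_proteins, x$n_cut_proteins, x$pct_cut_proteins, x$total_cuts,
    if (is.na(x$mean_cuts_per_cut_protein)) "-" else sprintf("%.2f", x$mean_cuts_per_cut_protein),
    x$n_fragments, x$n_skipped
  ))
  invisible(x)
}

# 60-column FASTA writer on an open connection (streaming path).
.write_fasta_con <- function(con, headers, seqs) {
  for (j in seq_along(headers)) {
    writeLines(paste0(">", headers[j]), con)
    s <- seqs[j]
    n <- nchar(s)
    writeLines(substring(s, seq(1L, n, 60L), pmin(seq(1L, n, 60L) + 59L, n)), con)
  }
}

#' Recompute digestion summary statistics from a product FASTA
#'
#' Parses the provenance headers written by [digest_proteome()] and
#' recomputes the per-run statistics (proteins with a cut, distinct cuts,
#' mean cuts per cut protein) from the output alone -- an audit of the
#' digestion run.
#'
#' @param path Product FASTA written by [digest_proteome()].
#' @return List with `n_cut_proteins`, `total_cuts` and
#'   `mean_cuts_per_cut_protein` as recomputed from headers.
#' @export
summarize_product_fasta <- function(path) {
  prods <- read_fasta(path)
  m <- regmatches(prods$id, regexec("^(.*)\\|frag\\|(\\d+)-(\\d+)\\|cut:([0-9,]*)\\|motif:", prods$id))
  parsed <- do.call(rbind, lapply(m, function(g) {
    if (length(g) == 0L) return(NULL)
    data.frame(parent = g[2], cuts = g[5], stringsAsFactors = FALSE)
  }))
  if (is.null(parsed)) {
    return(list(n_cut_proteins = 0L, total_cuts = 0L, mean_cuts_per_cut_protein = NA_real_))
  }
  per_parent <- lapply(split(parsed$cuts, parsed$parent), function(cc) {
    unique(as.integer(unlist(strsplit(cc[nzchar(cc)], ",", fixed = TRUE))))
  })
  ncuts <- lengths(per_parent)
  ncuts <- ncuts[ncuts > 0L]
  list(
    n_cut_proteins = length(ncuts),
    total_cuts = sum(ncuts),
    mean_cuts_per_cut_protein = if (length(ncuts)) mean(ncuts) else NA_real_
  )
}
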