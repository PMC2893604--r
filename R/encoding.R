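#' Window geometry around a candidate cut site
#'
#' A candidate site is indexed by its P1 residue (1-based); the cut falls
#' between P1 and P1'. A window takes `n_left` residues ending at P1 and
#' `n_right` residues starting at P1'. The geometry grids used for model
#' selection are `n_left` in 4, 6, ..., 16 and `n_right` in 0, 2, ..., 16,
#' but any `n_left >= 1`, `n_right >= 0` is accepted for general use.
#'
#' @param n_left Residues before the cut (P1 is the last of these).
#' @param n_right Residues after the cut.
#' @return A `window_geometry` object.
#' @export
#' @examples
#' window_geometry(6, 4) # the SVM-6-4 window
window_geometry <- function(n_left, n_right) {
  n_left <- as.integer(n_left)
  n_right <- as.integer(n_right)
  stopifnot(length(n_left) == 1L, length(n_right) == 1L,
            !is.na(n_left), !is.na(n_right), n_left >= 1L, n_right >= 0L)
  structure(list(n_left = n_left, n_right = n_right), class = "window_geometry")
}

#' @export
format.window_geometry <- function(x, ...) {
  sprintf("window %d-%d (length %d, %d features)",
          x$n_left, x$n_right, x$n_left + x$n_right, 20L * (x$n_left + x$n_right))
}

#' @export
print.window_geometry <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Extract the residue window around a candidate site
#'
#' Returns the `n_left + n_right` residue string around the cut after P1.
#' Near a terminus the window may overrun the sequence: with
#' `policy = "skip"` the site yields `NA` (used for training, where partial
#' windows are discarded); with `policy = "pad"` out-of-range positions are
#' filled with `-`, which encodes as an all-zero block (used for proteome
#' scanning so near-terminal sites are still evaluated).
#'
#' @param sequence Protein sequence string (or a single-row
#'   [protein_records()]).
#' @param p1 1-based position of the P1 residue.
#' @param geometry A [window_geometry()].
#' @param policy `"skip"` or `"pad"`.
#' @return Window string, or `NA_character_` when skipped.
#' @export
#' @examples
#' extract_window("ACDEVDGSKL", 6, window_geometry(4, 2)) # "DEVDGS"
extract_window <- function(sequence, p1, geometry, policy = c("skip", "pad")) {
  policy <- match.arg(policy)
  sequence <- .as_sequence(sequence)
  n <- nchar(sequence)
  if (any(p1 < 1L | p1 > n)) {
    stop("site position out of range [1, ", n, "]: ", p1[p1 < 1L | p1 > n][1])
  }
  from <- p1 - geometry$n_left + 1L
  to <- p1 + geometry$n_right
  if (policy == "skip") {
    out <- rep(NA_character_, length(p1))
    ok <- from >= 1L & to <= n
    if (any(ok)) out[ok] <- substring(sequence, from[ok], to[ok])
    return(out)
  }
  left_pad <- pmax(0L, 1L - from)
  right_pad <- pmax(0L, to - n)
  core <- substring(sequence, pmax(from, 1L), pmin(to, n))
  paste0(strrep("-", left_pad), core, strrep("-", right_pad))
}

.as_sequence <- function(x) {
  if (inherits(x, "protein_records")) {
    stopifnot(nrow(x) == 1L)
    return(x$sequence)
  }
  stopifnot(is.character(x), length(x) == 1L)
  x
}

#' One-hot encode site windows
#'
#' Each residue becomes a 20-element indicator block in the fixed
#' [aa_residues()] order; Val sets the first element, Ala the fifth. The
#' placeholder codes `-` (terminal padding) and `X` (unknown residue) encode
#' as all-zero blocks. Windows must share one length.
#'
#' @param windows Character vector of equal-length window strings.
#' @param geometry Optional [window_geometry()]; when supplied, column names
#'   carry the Schechter-Berger position labels (`P6_V` ... `P1_D`,
#'   `P1p_G` ...), and window length is checked against it.
#' @param residue_order Encoding order of the 20 residues; the default is
#'   the package's frozen table. Exposed so that the encoding-permutation
#'   symmetry can be exercised.
#' @return Integer matrix, one row per window, `20 * window length` columns.
#' @export
#' @examples
#' encode_windows("DEVDGS", window_geometry(4, 2))
encode_windows <- function(windows, geometry = NULL, residue_order = aa_residues()) {
  stopifnot(is.character(windows), !anyNA(windows))
  if (length(windows) == 0L) {
    L <- if (is.null(geometry)) 0L else geometry$n_left + geometry$n_right
    return(matrix(0L, 0L, 20L * L, dimnames = list(NULL, .feature_names(geometry, residue_order))))
  }
  L <- unique(nchar(windows))
  if (length(L) != 1L) {
    stop("windows must all have the same length")
  }
  if (!is.null(geometry) && L != geometry$n_left + geometry$n_right) {
    stop("window length ", L, " does not match ", format(geometry))
  }
  chars <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(windows), byrow = TRUE)
  idx <- match(chars, residue_order)
  unknown <- is.na(idx) & !(chars %in% .placeholder_chars)
  if (any(unknown)) {
    stop("unknown residue code '", chars[unknown][1], "' in window")
  }
  m <- matrix(0L, length(windows), 20L * L)
  hit <- which(!is.na(idx))
  row <- (hit - 1L) %% length(windows) + 1L
  pos <- (hit - 1L) %/% length(windows) + 1L
  m[cbind(row, (pos - 1L) * 20L + idx[hit])] <- 1L
  colnames(m) <- .feature_names(
    if (is.null(geometry)) NULL else geometry, residue_order, L
  )
  m
}

# Column labels: P<k>_<res> left of the cut, P<k>p_<res> (prime) right of it.
# Without a geometry, positions are labelled s1..sL.
.feature_names <- function(geometry, residue_order, L = NULL) {
  if (is.null(geometry)) {
    if (is.null(L) || L == 0L) return(NULL)
    labs <- paste0("s", seq_len(L))
  } else {
    labs <- c(
      if (geometry$n_left > 0L) paste0("P", geometry$n_left:1),
      if (geometry$n_right > 0L) paste0("P", seq_len(geometry$n_right), "p")
    )
  }
  as.vector(vapply(labs, function(l) paste0(l, "_", residue_order), character(20L)))
}

#' Enumerate candidate cut sites in a protein
#'
#' With a motif, only positions whose P1-anchored context matches are
#' emitted; the default motif `"D"` selects every Asp. Without a motif every
#' residue position is a candidate. When a geometry is given together with
#' `policy = "skip"`, sites whose window would overrun a terminus are
#' dropped.
#'
#' @param sequence Protein sequence string or single-row
#'   [protein_records()].
#' @param motif Motif pattern(s) anchored at P1 (see [motif_to_regex()]);
#'   `NULL` scans every position.
#' @param geometry Optional [window_geometry()] used only for `"skip"`
#'   filtering.
#' @param policy Terminal-window policy, `"pad"` (default, keep all sites)
#'   or `"skip"`.
#' @return Sorted integer vector of candidate P1 positions.
#' @export
#' @examples
#' scan_candidates("MKDGDA") # D at 3 and 5
scan_candidates <- function(sequence, motif = "D", geometry = NULL,
                            policy = c("pad", "skip")) {
  policy <- match.arg(policy)
  sequence <- .as_sequence(sequence)
  n <- nchar(sequence)
  if (is.null(motif)) {
    p1 <- seq_len(n)
  } else {
    p1 <- sort(unique(unlist(lapply(motif, function(m) {
      parsed <- motif_to_regex(m)
      hits <- gregexpr(paste0("(?=", parsed$regex, ")"), sequence, perl = TRUE)[[1]]
      if (hits[1] == -1L) return(integer(0))
      as.integer(hits) + parsed$length - 1L
    }))))
  }
  if (policy == "skip" && !is.null(geometry) && length(p1)) {
    p1 <- p1[p1 - geometry$n_left + 1L >= 1L & p1 + geometry$n_right <= n]
  }
  p1
}

#' Compile a P1-anchored motif pattern
#'
#' Motifs are written N- to C-terminal and end at P1: each position is a
#' single residue code, a bracketed class like `[WL]`, or `X`/`.` for any
#' residue. Examples: `"D"` (Asp at P1), `"DEXD"`, `"[WL]EHD"`,
#' `"[ILV]E[HT]D"`.
#'
#' @param motif Motif string.
#' @return List with the equivalent regular expression (`regex`) and the
#'   motif length in residues (`length`).
#' @export
motif_to_regex <- function(motif) {
  stopifnot(is.character(motif), length(motif) == 1L, nzchar(motif))
  chars <- strsplit(motif, "", fixed = TRUE)[[1]]
  tokens <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(j) || j == i + 1L) stop("malformed residue class in motif: ", motif)
      cls <- chars[(i + 1L):(j - 1L)]
      if (!all(cls %in% aa_residues())) stop("unknown residue in motif class: ", motif)
      tokens <- c(tokens, paste0("[", paste(cls, collapse = ""), "]"))
      i <- j + 1L
    } else if (chars[i] %in% c("X", ".")) {
      tokens <- c(tokens, "[A-Z]")
      i <- i + 1L
    } else if (chars[i] %in% aa_residues()) {
      tokens <- c(tokens, chars[i])
      i <- i + 1L
    } else {
      stop("unknown motif character '", chars[i], "' in motif: ", motif)
    }
  }
  list(regex = paste(tokens, collapse = ""), length = length(tokens))
}
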