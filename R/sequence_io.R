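#' Construct a set of protein records
#'
#' A `protein_records` object is a data frame with columns `id`,
#' `description` and `sequence`, the unit of FASTA input/output and
#' digestion.
#'
#' @param id Character vector of identifiers (first whitespace-delimited
#'   header token).
#' @param sequence Character vector of amino-acid sequences (upper case,
#'   20-letter alphabet plus the `X` placeholder).
#' @param description Optional character vector of header remainders.
#' @return A `protein_records` data frame.
#' @export
protein_records <- function(id, sequence, description = "") {
  stopifnot(length(id) == length(sequence))
  if (anyDuplicated(id)) {
    warning("duplicated protein ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  out <- data.frame(
    id = as.character(id),
    description = rep_len(as.character(description), length(id)),
    sequence = toupper(as.character(sequence)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("protein_records", "data.frame")
  out
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are normalised to upper case; line wrapping and trailing
#' whitespace are immaterial. By default any character outside the 20
#' standard one-letter codes is an error naming the offending record and
#' position; with `relaxed = TRUE` the non-standard codes B, Z, X, U, O, J
#' and `*` are substituted by the placeholder `X`, which encodes as an
#' all-zero (uninformative) block.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @param relaxed Substitute non-standard residue codes by `X` instead of
#'   rejecting the file.
#' @return A [protein_records()] data frame, one row per entry in file order.
#' @export
read_fasta <- function(path, relaxed = FALSE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  # tolerate stray whitespace (stripped before parsing), but refuse input
  # the FASTA parser would otherwise silently repair (digits, punctuation)
  clean <- tempfile(fileext = ".fasta")
  on.exit(unlink(clean))
  lines <- readLines(path, warn = FALSE)
  if (length(lines)) lines <- ifelse(startsWith(lines, ">"),
                  sub("[ \t\r]+$", "", lines),   # headers keep internal spaces
                  gsub("[ \t\r]+", "", lines))   # sequence lines drop all whitespace
  writeLines(lines, clean)
  set <- withCallingHandlers(
    Biostrings::readAAStringSet(clean),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("disallowed non-residue characters in FASTA file: ", path)
      }
      invokeRestart("muffleWarning")
    }
  )
  headers <- names(set)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for FASTA entry: ", headers[which(empty)[1]])
  }
  if (relaxed) {
    seqs <- chartr(
      paste(.nonstandard_codes, collapse = ""),
      strrep("X", length(.nonstandard_codes)),
      seqs
    )
  }
  # placeholder X is legal only after relaxed substitution
  pattern <- paste0("[^", if (relaxed) "X", paste(aa_residues(), collapse = ""), "]")
  bad <- grepl(pattern, seqs)
  if (any(bad)) {
    i <- which(bad)[1]
    pos <- regexpr(pattern, seqs[i])
    stop(
      "disallowed residue '", substr(seqs[i], pos, pos), "' at position ", pos,
      " in record '", ids[i], "'",
      if (!relaxed) " (use relaxed = TRUE to substitute non-standard codes)"
    )
  }
  out <- protein_records(ids, seqs, desc)
  # suppress the duplicate-id warning path: ids come from the file as-is
  out
}

#' Write protein records or cleavage products to FASTA
#'
#' Output is re-readable by [read_fasta()] with identical ids and sequences.
#' Sequences are wrapped at 60 columns. Cleavage products (see
#' [fragment_protein()]) are written with a deterministic provenance header
#' `>{parent}|frag|{start}-{end}|cut:{p1,...}|motif:{P4P3P2P1;...}` so that
#' downstream MS identifications can be traced to the predicted site.
#'
#' @param records A [protein_records()] or `cleavage_products` data frame.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(records, path) {
  headers <- fasta_headers(records)
  seqs <- records$sequence
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- headers
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

# Header line (without ">") for each record; products get provenance headers.
fasta_headers <- function(records) {
  if (inherits(records, "cleavage_products")) {
    sprintf(
      "%s|frag|%d-%d|cut:%s|motif:%s",
      records$parent_id, records$start, records$end,
      records$cuts_used, records$motif_context
    )
  } else {
    ifelse(
      nzchar(records$description),
      paste(records$id, records$description),
      records$id
    )
  }
}

#' Read a known-cut-site list
#'
#' Tab-separated file, one protein per line: `protein_id<TAB>p1,p1,...`
#' where each value is the 1-based position of a P1 residue (the cut falls
#' immediately C-terminal to it). Positions are stored sorted; duplicates
#' are collapsed with a warning. Lines starting with `#` and blank lines are
#' ignored. Range checking against a protein happens at digestion time.
#'
#' @param path Path to the TSV file.
#' @return Named list mapping protein id to a sorted integer vector of P1
#'   positions.
#' @export
read_known_sites <- function(path) {
  if (!file.exists(path)) {
    stop("known-sites file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  out <- list()
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2L || !nzchar(trimws(fields[1]))) {
      stop("malformed known-sites line ", i, ": expected 'id<TAB>pos,pos,...'")
    }
    id <- trimws(fields[1])
    pos <- suppressWarnings(as.integer(strsplit(trimws(fields[2]), ",", fixed = TRUE)[[1]]))
    if (length(pos) == 0L || anyNA(pos) || any(pos < 1L)) {
      stop("malformed known-sites line ", i, ": positions must be positive integers")
    }
    if (anyDuplicated(pos)) {
      warning("duplicate positions for '", id, "' collapsed")
    }
    pos <- sort(unique(pos))
    if (!is.null(out[[id]])) {
      warning("protein '", id, "' listed on multiple lines; positions merged")
      pos <- sort(unique(c(out[[id]], pos)))
    }
    out[[id]] <- pos
  }
  out
}

#' Load a training set of proteins plus annotated cut sites
#'
#' Convenience loader pairing a FASTA file of proteins with a known-sites
#' TSV of positive P1 positions (the on-disk form of a curated cleavage-site
#' training set).
#'
#' @param fasta_path FASTA file of protein sequences.
#' @param sites_path TSV of positive P1 positions per protein id.
#' @param relaxed Passed to [read_fasta()].
#' @return List with elements `proteins` ([protein_records()]) and
#'   `positive_sites` (named list of integer vectors).
#' @export
read_training_set <- function(fasta_path, sites_path, relaxed = FALSE) {
  proteins <- read_fasta(fasta_path, relaxed = relaxed)
  sites <- read_known_sites(sites_path)
  unknown <- setdiff(names(sites), proteins$id)
  if (length(unknown)) {
    stop("cut sites reference proteins absent from the FASTA: ",
         paste(unknown, collapse = ", "))
  }
  list(proteins = proteins, positive_sites = sites)
}
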