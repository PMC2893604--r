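#' Standard amino-acid alphabet and one-hot index table
#'
#' Each residue in a site window is encoded as a 20-element indicator block;
#' the position of the single 1 within the block is given by this fixed
#' residue ordering. The ordering places Val at index 1 and Ala at index 5
#' (aliphatic residues first, charged/acidic last). Any fixed ordering gives
#' an equivalent classifier -- permuting one-hot blocks is a relabeling of
#' columns -- but the table is frozen so that saved models and encodings are
#' stable across sessions.
#'
#' @return Character vector of the 20 standard one-letter residue codes in
#'   encoding order.
#' @export
#' @examples
#' match("A", aa_residues()) # Ala occupies the 5th slot of its block
aa_residues <- function() {
  c("V", "L", "I", "M", "A", "F", "W", "Y", "G", "P",
    "S", "T", "C", "H", "R", "K", "Q", "E", "N", "D")
}

# Placeholder codes that encode as an all-zero block: "-" marks terminal
# padding, "X" an unknown/non-standard residue admitted under relaxed parsing.
.placeholder_chars <- c("-", "X")

# Non-standard codes that `relaxed` FASTA parsing maps to the placeholder.
.nonstandard_codes <- c("B", "Z", "X", "U", "O", "J", "*")

.is_valid_sequence <- function(s) {
  !grepl(paste0("[^", paste(aa_residues(), collapse = ""), "]"), s)
}
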