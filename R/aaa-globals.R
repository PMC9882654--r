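## Residue vocabulary shared across modules.  'X' is tolerated on input but
## always counts as mismatch / zero charge / non-motif.
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_ALLOWED <- c(AA20, "X")
BASIC <- c("K", "R")
ACIDIC <- c("D", "E")
HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "Y")

split1 <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

check_residues <- function(residues, id = "<sequence>") {
  chars <- split1(residues)
  bad <- which(!chars %in% AA_ALLOWED)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "record '%s' contains invalid residue '%s' at position %d",
      id, chars[bad[1]], bad[1]
    ), class = "rasevol_alphabet_error")
  }
  invisible(residues)
}
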