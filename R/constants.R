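# The 20 standard amino acids in fixed alphabetical (one-letter) order.
# Every 20-long feature block in the package is indexed by this vector.
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Three-letter -> one-letter residue codes for the standard 20.
AA_THREE_TO_ONE <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y"
)

# Hydrophobic subset used by the synthetic generator's contact signal.
AA_HYDROPHOBIC <- c("A", "V", "I", "L", "M", "F", "W", "C")

#' The amino-acid alphabet used throughout the package
#'
#' @return Character vector of the 20 standard one-letter codes, in the
#'   fixed alphabetical order that indexes every composition and one-hot
#'   feature block.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() AA_ALPHABET

is_standard_aa <- function(x) x %in% AA_ALPHABET

# index in AA_ALPHABET or NA
aa_index <- function(x) match(x, AA_ALPHABET)
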