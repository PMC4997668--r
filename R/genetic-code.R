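#' The standard genetic code with its synonymous-family structure
#'
#' Returns one row per codon of the standard nuclear genetic code, annotated
#' with the synonymy structure used throughout the package: the 59 "sense"
#' codons — every codon except Met (AUG), Trp (UGG) and the three stops —
#' are partitioned into 18 synonymous families keyed by amino acid. The
#' six-fold amino acids (Leu, Ser, Arg) are kept as single families of six,
#' so the degeneracy multiset is 9 two-fold, 1 three-fold (Ile), 5 four-fold
#' and 3 six-fold families.
#'
#' @return A tibble with columns:
#'   \describe{
#'     \item{codon}{DNA codon (e.g. `"TTT"`).}
#'     \item{codon_rna}{RNA spelling (`"UUU"`), used in all reports.}
#'     \item{aa}{one-letter amino acid, `"*"` for stop.}
#'     \item{amino_acid}{three-letter amino acid name, `"Stop"` for stops.}
#'     \item{family}{family key (the three-letter name) for the 59 sense
#'       codons, `NA` for Met, Trp and stops.}
#'     \item{degeneracy}{family size (2/3/4/6), `NA` outside families.}
#'     \item{third_base}{RNA third base.}
#'     \item{gc_ending}{`TRUE` when the third base is G or C.}
#'   }
#' @examples
#' code <- genetic_code()
#' sum(!is.na(code$family))      # 59 sense codons
#' table(code$degeneracy[!duplicated(code$family) & !is.na(code$family)])
#' @export
genetic_code <- function() {
  .codonuse_code
}

.aa3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Stop"
)

.build_genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  codon <- names(gc)
  aa <- unname(gc)
  amino_acid <- unname(.aa3[aa])
  family <- ifelse(aa %in% c("M", "W", "*"), NA_character_, amino_acid)
  fam_sizes <- table(family[!is.na(family)])
  tibble::tibble(
    codon = codon,
    codon_rna = chartr("T", "U", codon),
    aa = aa,
    amino_acid = amino_acid,
    family = family,
    degeneracy = ifelse(is.na(family), NA_integer_,
                        as.integer(fam_sizes[family])),
    third_base = substr(chartr("T", "U", codon), 3, 3),
    gc_ending = substr(codon, 3, 3) %in% c("G", "C")
  )
}

# one copy built at install time; genetic_code() hands it out
.codonuse_code <- .build_genetic_code()

#' Sense codons of the standard code
#'
#' Convenience accessor for the 59-codon universe (all synonymously variable
#' codons; Met, Trp and stops excluded).
#'
#' @return A tibble, the subset of [genetic_code()] rows with a family.
#' @export
sense_codons <- function() {
  code <- genetic_code()
  code[!is.na(code$family), , drop = FALSE]
}
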