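# IUPAC ambiguity-code algebra for diploid consensus calls.
#
# The pipeline is bi-allelic: a consensus character is a homozygous base
# (A/C/G/T), one of the six two-base ambiguity codes (R/Y/S/W/K/M), a
# homozygous single-base deletion ('-'), a heterozygous base/deletion call
# (lowercase base -- an artifact convention, see the vignette), or N
# (no call / missing).

.IUPAC2 <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC")

#' Decode an IUPAC consensus character into its allele set
#'
#' @param code single character: `A C G T R Y S W K M N -`.
#' @return character vector of alleles: length 1 for A/C/G/T/`-`, length 2
#'   for ambiguity codes, length 0 for `N` (no call).
#' @seealso [iupac_encode()]
#' @export
iupac_decode <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 1L)
    stop("iupac_decode expects a single character")
  if (code %in% c("A", "C", "G", "T", "-")) return(code)
  if (code == "N") return(character(0))
  if (code %in% names(.IUPAC2)) return(chars(.IUPAC2[[code]]))
  stop("unknown IUPAC character '", code, "'")
}

#' Encode an allele set as an IUPAC consensus character
#'
#' Inverse of [iupac_decode()] on the twelve supported codes. Sets of three
#' or more alleles are rejected: the pipeline models bi-allelic sites only.
#'
#' @param alleles character vector of 1 or 2 alleles from `A C G T -`.
#' @return single character.
#' @export
iupac_encode <- function(alleles) {
  alleles <- sort(unique(as.character(alleles)))
  if (length(alleles) == 0L) return("N")
  if (!all(alleles %in% c("A", "C", "G", "T", "-")))
    stop("alleles must be A/C/G/T/-")
  if (length(alleles) == 1L) return(alleles)
  if (length(alleles) > 2L)
    stop("sets of ", length(alleles), " alleles are unsupported (bi-allelic model)")
  if ("-" %in% alleles) {
    # base/gap heterozygote: lowercase-base artifact convention
    return(tolower(setdiff(alleles, "-")))
  }
  key <- paste(alleles, collapse = "")
  hit <- names(.IUPAC2)[match(key, .IUPAC2)]
  if (is.na(hit)) stop("no IUPAC code for allele pair ", key)
  hit
}

# Decode one panel consensus character into a diploid genotype:
# returns c(a1, a2) over alleles {A,C,G,T,-}, or NULL for a missing call.
decode_genotype <- function(code) {
  if (code == "N") return(NULL)
  if (code %in% c("A", "C", "G", "T", "-")) return(c(code, code))
  if (code %in% names(.IUPAC2)) return(chars(.IUPAC2[[code]]))
  if (code %in% c("a", "c", "g", "t")) return(c(toupper(code), "-"))
  stop("unknown consensus character '", code, "'")
}

# Encode a diploid genotype (two alleles over {A,C,G,T,-}) as one character.
encode_genotype <- function(a1, a2) {
  if (a1 == a2) return(a1)
  iupac_encode(c(a1, a2))
}
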