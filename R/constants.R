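# Amino-acid alphabet and physicochemical wildcard classes.
#
# Only the 20 standard residues (uppercase) plus the gap character '-' are
# admitted in alignments; ambiguity codes (B, Z, X, U, O) are rejected at
# load so every downstream denominator is unambiguous.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHAR <- "-"

GPCR_CLASSES <- c("A", "B", "C", "F")

TAXON_GROUPS <- c("human", "mammal", "vertebrate", "eukaryote", "other")

# Cumulative taxonomic selection sets: Human < Mammals < Vertebrates <
# Eukaryotes < All.
TAXON_SETS <- list(
  Human       = "human",
  Mammals     = c("human", "mammal"),
  Vertebrates = c("human", "mammal", "vertebrate"),
  Eukaryotes  = c("human", "mammal", "vertebrate", "eukaryote"),
  All         = c("human", "mammal", "vertebrate", "eukaryote", "other")
)

WILDCARD_CLASSES <- list(
  "X" = AA_ALPHABET,                                   # any amino acid
  "@" = c("W", "Y", "F", "H"),                         # aromatic
  "~" = c("I", "L", "V", "A", "F", "P"),               # apolar
  "+" = c("R", "H", "K"),                              # positively charged
  "-" = c("D", "E"),                                   # negatively charged
  "*" = c("R", "H", "K", "D", "E"),                    # charged
  "^" = c("D", "E", "N", "Q", "K", "R", "H",
          "S", "T", "C", "W", "Y")                     # polar
)

#' Physicochemical wildcard classes for motif strings
#'
#' The seven one-character wildcards usable in motif patterns, each mapping
#' to a set of one-letter amino-acid codes: `X` (any), `@` (aromatic:
#' W/Y/F/H), `~` (apolar: I/L/V/A/F/P), `+` (positively charged: R/H/K),
#' `-` (negatively charged: D/E), `*` (charged: R/H/K/D/E) and `^` (polar:
#' D/E/N/Q/K/R/H/S/T/C/W/Y). Classes may overlap (e.g. F is both aromatic
#' and apolar); `*` is the union of `+` and `-`.
#'
#' @return Named list of character vectors, one per wildcard.
#' @examples
#' wildcard_classes()[["@"]]
#' @export
wildcard_classes <- function() {
  WILDCARD_CLASSES
}

# Classed error helper: every condition carries "gpcralign_error" plus a
# specific subclass that tests and callers can dispatch on.
gpcr_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "gpcralign_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
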