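#' The six strand-collapsed base-pair substitution types
#'
#' Because the two strands of duplex DNA are complementary, the twelve
#' directional single-base changes collapse onto six base-pair substitution
#' categories: a C>T change on one strand is the same base-pair event as G>A
#' on the other, and both are written `"GC>AT"`.  Two of the six are
#' transitions (`"AT>GC"`, `"GC>AT"`); the other four are transversions.
#'
#' @return Character vector of the six type labels, in the package's
#'   canonical order.
#' @examples
#' mutation_types()
#' @export
mutation_types <- function() {
  c("AT>GC", "AT>CG", "AT>TA", "GC>AT", "GC>TA", "GC>CG")
}

#' @rdname mutation_types
#' @return For `transition_types()`, the two transition labels.
#' @export
transition_types <- function() {
  c("AT>GC", "GC>AT")
}

dna_bases <- c("A", "C", "G", "T")

complement_base <- function(x) {
  chartr("ACGT", "TGCA", x)
}

reverse_complement <- function(x) {
  vapply(
    x,
    function(s) {
      paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
            collapse = "")
    },
    character(1),
    USE.NAMES = FALSE
  )
}

#' Classify a base change into its strand-collapsed substitution type
#'
#' Vectorised over `ref` and `alt`.  The category names the ancestral
#' base pair first: both `C>T` and `G>A` map to `"GC>AT"`, both `A>C`
#' and `T>G` map to `"AT>CG"`, and so on.  The map from the twelve
#' directional changes onto the six categories is total and two-to-one.
#'
#' @param ref,alt Single reference and alternate bases (`"A"`, `"C"`,
#'   `"G"` or `"T"`); `ref != alt` elementwise.
#' @return Character vector of type labels (see [mutation_types()]).
#' @examples
#' classify_type("C", "T")  # "GC>AT", a transition
#' classify_type("T", "G")  # "AT>CG", a transversion
#' @export
classify_type <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (!all(ref %in% dna_bases) || !all(alt %in% dna_bases)) {
    abort("`ref` and `alt` must be single bases in {A, C, G, T}.")
  }
  if (any(ref == alt)) {
    abort("`ref` and `alt` must differ: a substitution changes the base.")
  }
  # collapse onto the strand carrying the purine of the ancestral pair
  flip <- ref %in% c("T", "C")
  r <- ifelse(flip, complement_base(ref), ref)
  a <- ifelse(flip, complement_base(alt), alt)
  key <- paste0(r, a)
  map <- c(
    AG = "AT>GC", AC = "AT>CG", AT = "AT>TA",
    GA = "GC>AT", GT = "GC>TA", GC = "GC>CG"
  )
  unname(map[key])
}

#' @rdname classify_type
#' @param type Character vector of type labels.
#' @return For `is_transition()`, a logical vector: `TRUE` for the two
#'   transition categories.
#' @export
is_transition <- function(type) {
  type %in% transition_types()
}

# "AT" or "GC": the ancestral base pair a type mutates away from
type_origin <- function(type) {
  substr(type, 1, 2)
}
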