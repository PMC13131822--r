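# Stranded trinucleotide substitution channels.
#
# 192 channels = 6 pyrimidine-centred substitutions x 16 flanking-base pairs
# x 2 strand orientations. Orientation "+" means the pyrimidine of the mutated
# base pair lies on the reference strand; "-" means it lies on the reverse
# strand (the reference shows the purine). Channel m maps to index
# (orientation - 1) * 96 + (sub - 1) * 16 + (five - 1) * 4 + three.

MUT_BASES <- c("A", "C", "G", "T")
MUT_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
MUT_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Number of stranded mutation-type channels
#' @return Integer, 192.
#' @export
n_mutation_types <- function() 192L

.type_table <- local({
  grid <- expand.grid(three = MUT_BASES, five = MUT_BASES, sub = MUT_SUBS,
                      orient = c("+", "-"), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("orient", "sub", "five", "three")]
  ref <- substr(grid$sub, 1, 1)
  grid$context <- paste0(grid$five, ref, grid$three)
  grid$label <- paste0(grid$five, "[", grid$sub, "]", grid$three, ":",
                       grid$orient)
  grid$index <- seq_len(nrow(grid))
  grid
})

#' Labels of the 192 stranded mutation-type channels
#'
#' Labels follow the `5'[REF>ALT]3':strand` convention, e.g. `"T[C>A]G:+"`.
#' The first 96 channels carry orientation `+` (pyrimidine on the reference
#' strand) in COSMIC substitution-major order; the last 96 repeat them with
#' orientation `-`.
#' @return Character vector of length 192.
#' @export
mutation_type_labels <- function() .type_table$label

#' Labels of the 96 collapsed (strand-agnostic) channels
#' @return Character vector of length 96.
#' @export
mutation_type_labels_96 <- function() {
  sub(":\\+$", "", .type_table$label[1:96])
}

.revcomp_chr <- function(x) {
  vapply(strsplit(x, ""), function(b) {
    paste(rev(unname(MUT_COMPLEMENT[b])), collapse = "")
  }, character(1))
}

#' Resolve the stranded channel of a mutation
#'
#' @param ref Reference base(s) at the mutated position (A/C/G/T).
#' @param alt Alternate base(s).
#' @param context Reference-strand trinucleotide centred on the position.
#' @return Integer vector of channel indices in 1..192; `NA` where the
#'   context contains ambiguous bases or does not match `ref`.
#' @export
mutation_type_index <- function(ref, alt, context) {
  n <- length(ref)
  stopifnot(length(alt) == n, length(context) == n)
  ref <- toupper(ref); alt <- toupper(alt); context <- toupper(context)
  context[is.na(context)] <- "NNN"
  out <- rep(NA_integer_, n)
  ok <- !is.na(ref) & !is.na(alt) & ref %in% MUT_BASES &
    alt %in% MUT_BASES & ref != alt &
    nchar(context) == 3L & !grepl("[^ACGT]", context) &
    substr(context, 2, 2) == ref
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(out)
  r <- ref[ok]; a <- alt[ok]; ctx <- context[ok]
  pyr <- r %in% c("C", "T")
  sub <- ifelse(pyr, paste0(r, ">", a),
                paste0(MUT_COMPLEMENT[r], ">", MUT_COMPLEMENT[a]))
  ctx_or <- ctx
  if (any(!pyr)) ctx_or[!pyr] <- .revcomp_chr(ctx[!pyr])
  orient <- ifelse(pyr, "+", "-")
  key <- paste0(substr(ctx_or, 1, 1), "[", sub, "]", substr(ctx_or, 3, 3),
                ":", orient)
  out[ok] <- match(key, .type_table$label)
  out
}

# 64 x 192 0/1 matrix: trinucleotide (Biostrings order, alphabetical) ->
# the three channels whose context that trinucleotide provides. A position
# with reference trinucleotide `tri` can host exactly the three substitutions
# of its oriented (pyrimidine-centred) context, in one orientation.
.tri_names <- sort(apply(expand.grid(MUT_BASES, MUT_BASES, MUT_BASES)[, 3:1],
                         1, paste, collapse = ""))

.tri_to_type <- local({
  M <- matrix(0, nrow = 64, ncol = 192,
              dimnames = list(.tri_names, .type_table$label))
  for (tri in .tri_names) {
    centre <- substr(tri, 2, 2)
    if (centre %in% c("C", "T")) {
      ctx <- tri; orient <- "+"
    } else {
      ctx <- .revcomp_chr(tri); orient <- "-"
    }
    hit <- .type_table$context == ctx & .type_table$orient == orient
    M[tri, hit] <- 1
  }
  M
})

#' Collapse a 192-channel vector or matrix to 96 strand-agnostic channels
#'
#' Sums the two strand orientations of each pyrimidine-centred channel.
#' Total mass is conserved exactly.
#'
#' @param x Numeric vector of length 192, or a matrix with 192 columns.
#' @return Vector of length 96 or matrix with 96 columns.
#' @export
collapse_to_96 <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 192L)
    out <- x[, 1:96, drop = FALSE] + x[, 97:192, drop = FALSE]
    colnames(out) <- mutation_type_labels_96()
    return(out)
  }
  stopifnot(length(x) == 192L)
  out <- x[1:96] + x[97:192]
  names(out) <- mutation_type_labels_96()
  out
}

#' Strand orientation sign of each channel
#'
#' @return Numeric vector of length 192: +1 for reference-strand pyrimidine
#'   channels, -1 for reverse-orientation channels. Used to couple
#'   strand-oriented features to the spectrum adjustment term.
#' @export
type_strand_sign <- function() {
  c(rep(1, 96), rep(-1, 96))
}

# Index permutation that swaps the two orientations of every channel.
.strand_swap_index <- function() c(97:192, 1:96)
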