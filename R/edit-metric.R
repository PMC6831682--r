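# Slot-wise distance over the C_G_V_X_T schema. An empty slot is a comparable
# symbol, so addition/deletion of a segment is one differing slot, exactly
# like a substitution; tone substitution counts as one unit as well.

.recycle_pair <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == nb) return(list(a = a, b = b))
  if (na == 1L) return(list(a = a[rep(1L, nb), ], b = b))
  if (nb == 1L) return(list(a = a, b = b[rep(1L, na), ]))
  stop("syllable tables must have equal row counts (or one row)", call. = FALSE)
}

.slot_differs <- function(x, y) {
  (is.na(x) != is.na(y)) | (!is.na(x) & !is.na(y) & x != y)
}

#' Phonological edit distance between syllables
#'
#' The number of differing slots among \{C, G, V, X, T\}, comparing an empty
#' slot against a filled one as a difference. This slot-wise (Hamming-style)
#' reading reproduces the segment/tone addition, deletion and substitution
#' operations of one-step phonological neighbourhood: two syllables are
#' immediate neighbours iff their distance is 1.
#'
#' Both arguments are syllable tibbles from [parse_pinyin()]; rows are paired
#' elementwise, with a single-row table recycled against the other.
#'
#' @param a,b Syllable tibbles with equal row counts (or one of them 1 row).
#' @return Integer vector of distances in `0:5`.
#' @examples
#' m <- pinyin_mapping()
#' edit_distance(parse_pinyin("wai4", m), parse_pinyin("shuan4", m))  # 2
#' @export
edit_distance <- function(a, b) {
  p <- .recycle_pair(a, b)
  d <- .slot_differs(p$a$T, p$b$T)
  for (s in .slot_cols) d <- d + .slot_differs(p$a[[s]], p$b[[s]])
  as.integer(d)
}

#' Graded fluency weight of a syllable pair
#'
#' The weight is the proportion of the edit steps still available before the
#' pair would share no similarity: with `U` the unit count of the longer item
#' and `e` the slot-wise edit distance, the weight is `(U - e) / (U - 1)`
#' clipped into `[0, 1]` (so identical items, edit 0, sit at the top of the
#' scale with weight 1). For a 4-unit stimulus with 5-unit responses
#' this yields the schedule 1, 0.75, 0.50, 0.25, 0 at edits 1-5; for a 3-unit
#' stimulus with 2-unit responses it yields 1, 0.50, 0. Identical items
#' (edit 0) sit at the top of the scale with weight 1.
#'
#' @inheritParams edit_distance
#' @return Numeric vector of weights in `[0, 1]`.
#' @examples
#' m <- pinyin_mapping()
#' edit_weight(parse_pinyin("wai4", m), parse_pinyin("xiang4", m))  # 0.5
#' @export
edit_weight <- function(a, b) {
  p <- .recycle_pair(a, b)
  U <- pmax(unit_count(p$a), unit_count(p$b))
  e <- edit_distance(p$a, p$b)
  pmin(1, pmax(0, (U - e) / (U - 1)))
}

#' Immediate phonological neighbour predicate
#'
#' `TRUE` where the slot-wise edit distance is exactly 1 (one segment or tone
#' added, deleted, or substituted). Identical syllables are not neighbours.
#'
#' @inheritParams edit_distance
#' @return Logical vector.
#' @export
is_immediate_neighbor <- function(a, b) {
  edit_distance(a, b) == 1L
}

#' Syllable neighbour predicate
#'
#' `TRUE` where two syllables share the same atonal base (equal C, G, V, X),
#' i.e. they belong to the same tone family. Identical syllables qualify,
#' which makes exact repetitions count as syllable neighbours in the
#' successive-pair proportion SN.
#'
#' @inheritParams edit_distance
#' @return Logical vector.
#' @export
is_syllable_neighbor <- function(a, b) {
  p <- .recycle_pair(a, b)
  atonal_key(p$a) == atonal_key(p$b)
}
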