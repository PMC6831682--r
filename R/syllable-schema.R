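#' Load a pinyin-to-slot mapping table
#'
#' Reads a two-column delimited table mapping atonal pinyin strings to the
#' five-slot Mandarin syllable schema C_G_V_X_T: onset consonant (C), glide
#' (G), nucleus vowel (V), coda (X), with the lexical tone (T) carried by the
#' trailing digit of a tonal pinyin string rather than by the mapping. Slot
#' assignments are written `C|G|V|X` with `-` marking an empty slot, e.g.
#' `wai` is `-|u|a|ɪ` (a GVX syllable with no onset).
#'
#' The packaged default covers the syllables used in the package examples and
#' fixtures. Segmentation of arbitrary pinyin is deliberately delegated to a
#' user-supplied table (e.g. one exported from a Mandarin neighbourhood
#' database): orthographic conventions such as `w`/`y` spellings are resolved
#' by the table, not by rule (`wu` is a bare-vowel syllable, `ye` is
#' glide + vowel).
#'
#' @param path Path to a UTF-8 tab-separated file with columns `pinyin` and
#'   `slots`. `NULL` (default) loads the packaged table.
#' @return A tibble with columns `pinyin`, `C`, `G`, `V`, `X` (`NA` = empty
#'   slot).
#' @examples
#' pinyin_mapping()
#' @export
pinyin_mapping <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pinyin_cgvx.tsv", package = "phonofluency")
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("pinyin", "slots") %in% names(raw))) {
    stop("mapping file must have columns 'pinyin' and 'slots'", call. = FALSE)
  }
  if (anyDuplicated(raw$pinyin)) {
    stop("mapping file contains duplicate pinyin entries", call. = FALSE)
  }
  slots <- stringr::str_split_fixed(raw$slots, stringr::fixed("|"), 4)
  bad <- slots[, 3] %in% c("-", "")
  if (any(bad)) {
    stop("mapping entries without a nucleus vowel: ",
         paste(raw$pinyin[bad], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    pinyin = raw$pinyin,
    C = dplyr::na_if(slots[, 1], "-"),
    G = dplyr::na_if(slots[, 2], "-"),
    V = slots[, 3],
    X = dplyr::na_if(slots[, 4], "-")
  )
  out
}

.slot_cols <- c("C", "G", "V", "X")

#' Parse tonal pinyin strings into the five-slot syllable schema
#'
#' Splits each string into its atonal base and trailing tone digit, then looks
#' the base up in the mapping table. The result is one row per input string
#' with the four segmental slots and the tone, the representation on which all
#' edit-distance and network computations operate.
#'
#' @param x Character vector of tonal pinyin strings, each ending in a tone
#'   digit 1-5 (5 = neutral tone).
#' @param mapping A slot mapping as returned by [pinyin_mapping()].
#' @return A tibble with columns `pinyin` (the input), `C`, `G`, `V`, `X`
#'   (character, `NA` = empty slot) and `T` (integer tone).
#' @examples
#' parse_pinyin(c("wai4", "du2", "wu2"))
#' @export
parse_pinyin <- function(x, mapping = pinyin_mapping()) {
  x <- as.character(x)
  tone_chr <- stringr::str_sub(x, -1)
  ok_tone <- stringr::str_detect(x, "^.+[1-5]$")
  if (any(!ok_tone)) {
    stop("missing or invalid tone digit in: ",
         paste(unique(x[!ok_tone]), collapse = ", "), call. = FALSE)
  }
  base <- stringr::str_sub(x, 1, -2)
  idx <- match(base, mapping$pinyin)
  if (anyNA(idx)) {
    stop("unknown atonal syllable(s): ",
         paste(unique(x[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    pinyin = x,
    C = mapping$C[idx],
    G = mapping$G[idx],
    V = mapping$V[idx],
    X = mapping$X[idx],
    T = as.integer(tone_chr)
  )
}

#' Render parsed syllables back to tonal pinyin
#'
#' Reverse lookup of slot assignments in the mapping table, with the tone
#' digit re-appended. `render_pinyin(parse_pinyin(s))` reproduces `s` for any
#' string covered by the mapping.
#'
#' @param syl A syllable tibble as returned by [parse_pinyin()].
#' @inheritParams parse_pinyin
#' @return Character vector of tonal pinyin strings.
#' @export
render_pinyin <- function(syl, mapping = pinyin_mapping()) {
  key <- function(C, G, V, X) {
    paste(dplyr::coalesce(C, "-"), dplyr::coalesce(G, "-"),
          V, dplyr::coalesce(X, "-"), sep = "|")
  }
  map_key <- key(mapping$C, mapping$G, mapping$V, mapping$X)
  idx <- match(key(syl$C, syl$G, syl$V, syl$X), map_key)
  if (anyNA(idx)) {
    stop("slot combination(s) not present in mapping", call. = FALSE)
  }
  paste0(mapping$pinyin[idx], syl$T)
}

#' Number of phonological units in a syllable
#'
#' The unit count is the number of filled segmental slots among C, G, V, X
#' plus one for the lexical tone; it ranges from 2 (bare vowel, e.g. `wu2`)
#' to 5 (full CGVX syllable, e.g. `shuai4`). The unit count of the longer
#' member of a pair sets the step size of the graded edit weighting.
#'
#' @inheritParams render_pinyin
#' @return Integer vector of unit counts in `2:5`.
#' @examples
#' unit_count(parse_pinyin(c("wai4", "shuai4", "wu2")))  # 4, 5, 2
#' @export
unit_count <- function(syl) {
  filled <- !is.na(as.matrix(syl[, .slot_cols]))
  as.integer(rowSums(filled)) + 1L
}

#' Atonal syllable identity
#'
#' Collapses a parsed syllable to its tone-independent identity (the C, G, V,
#' X slots). Two productions sharing an atonal key are *syllable neighbours*:
#' the same base syllable under different lexical tones (e.g. `ma1` and
#' `ma3`). The key partitions any syllable set into tone families.
#'
#' @inheritParams render_pinyin
#' @return Character vector of atonal keys, one per row of `syl`.
#' @examples
#' atonal_key(parse_pinyin(c("ma1", "ma3")))
#' @export
atonal_key <- function(syl) {
  paste(dplyr::coalesce(syl$C, "-"), dplyr::coalesce(syl$G, "-"),
        syl$V, dplyr::coalesce(syl$X, "-"), sep = "|")
}
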