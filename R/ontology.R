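#' The 17-class morphokinetic stage ontology
#'
#' Canonical ordered label set for pre-implantation embryo development as
#' scored on time-lapse imaging: polar-body appearance (`tPB2`), pronuclei
#' appearance/fading (`tPNa`, `tPNf`), cleavage stages `t2`..`t8` and `t9+`,
#' morula (`tM`), blastulation stages (`tSB`, `tB`, `tEB`, `tHB`) and the
#' data-quality class `Empty` (well after embryo removal). `Empty` is a well
#' state, not a developmental event, and is therefore placed last and
#' excluded from developmental adjacency.
#'
#' @return `stage_levels()` returns the 17 canonical label strings in
#'   developmental order; `stage_ontology()` returns a data.frame with
#'   columns `name`, `ordinal` (0-based, respecting developmental order),
#'   `description` and `rare` (`TRUE` for `tHB`, which has too few examples
#'   to evaluate reliably and is excluded from metrics by default).
#' @examples
#' stage_levels()
#' stage_ontology()
#' @export
stage_levels <- function() {
  c("tPB2", "tPNa", "tPNf", "t2", "t3", "t4", "t5", "t6", "t7", "t8",
    "t9+", "tM", "tSB", "tB", "tEB", "tHB", "Empty")
}

#' @rdname stage_levels
#' @export
stage_ontology <- function() {
  data.frame(
    name = stage_levels(),
    ordinal = 0:16,
    description = c(
      "Polar body appearance",
      "Pronuclei appearance",
      "Pronuclei disappearance",
      "Cleavage stage 2 cells",
      "Cleavage stage 3 cells",
      "Cleavage stage 4 cells",
      "Cleavage stage 5 cells",
      "Cleavage stage 6 cells",
      "Cleavage stage 7 cells",
      "Cleavage stage 8 cells",
      "Cleavage stage more than 9 cells",
      "Morula",
      "Start of Blastulation",
      "Blastocyst",
      "Expanded blastocyst",
      "Hatched blastocyst",
      "Empty well"
    ),
    rare = stage_levels() == "tHB",
    stringsAsFactors = FALSE
  )
}

# aliases accepted on input; canonical form is always emitted
.stage_aliases <- c("t9plus" = "t9+", "t9 +" = "t9+")

#' Parse morphokinetic stage labels
#'
#' Converts label strings to a factor over the canonical 17-level ontology.
#' Canonical names are matched case-sensitively; the documented aliases
#' `"t9plus"` and `"t9 +"` map to `"t9+"` (convenient for file formats that
#' cannot carry `+` in identifiers).
#'
#' @param text character vector of label names.
#' @return factor with levels `stage_levels()`.
#' @examples
#' parse_label(c("t2", "Empty", "t9plus"))
#' @export
parse_label <- function(text) {
  if (is.factor(text)) text <- as.character(text)
  if (!is.character(text)) {
    stop("labels must be supplied as character strings", call. = FALSE)
  }
  canon <- text
  hit <- canon %in% names(.stage_aliases)
  canon[hit] <- .stage_aliases[canon[hit]]
  bad <- !(canon %in% stage_levels())
  if (any(bad)) {
    stop(sprintf(
      "unknown stage label(s): %s (expected one of %s)",
      paste(sQuote(unique(text[bad])), collapse = ", "),
      paste(stage_levels(), collapse = ", ")
    ), call. = FALSE)
  }
  factor(canon, levels = stage_levels())
}

#' Stage ordinal and developmental adjacency
#'
#' `stage_ordinal()` maps labels to their 0-based position in the
#' developmental order. `is_adjacent()` reports whether two stages are
#' consecutive developmental stages (ordinal difference of exactly 1 among
#' the 16 developmental stages). `Empty` denotes a well state rather than a
#' stage and is adjacent to nothing.
#'
#' @param label,a,b stage labels (character or factor; parsed via
#'   [parse_label()]).
#' @return `stage_ordinal()`: integer vector in 0..16; `is_adjacent()`:
#'   logical vector.
#' @examples
#' stage_ordinal("t2")
#' is_adjacent("t4", "t5")
#' is_adjacent("tEB", "Empty")
#' @export
stage_ordinal <- function(label) {
  as.integer(parse_label(label)) - 1L
}

#' @rdname stage_ordinal
#' @export
is_adjacent <- function(a, b) {
  a <- parse_label(a)
  b <- parse_label(b)
  abs(stage_ordinal(a) - stage_ordinal(b)) == 1L &
    a != "Empty" & b != "Empty"
}
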