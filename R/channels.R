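#' Channel schemas for mutation spectra
#'
#' A channel schema is an ordered set of unique mutation-type labels. The
#' built-in SBS96 schema classifies single-base substitutions by the
#' substituted pyrimidine (C or T), its replacement, and the two flanking
#' bases, in the conventional COSMIC ordering: substitution class
#' (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank, then 3' flank.
#'
#' @param name schema identifier.
#' @param channels character vector of unique channel labels; order is
#'   significant.
#' @return An object of class `channel_schema`.
#' @export
#' @examples
#' sch <- sbs96_schema()
#' length(sch$channels)  # 96
channel_schema <- function(name, channels) {
  channels <- as.character(channels)
  if (anyDuplicated(channels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  if (length(channels) == 0L) {
    stop("a schema needs at least one channel", call. = FALSE)
  }
  structure(list(name = name, channels = channels), class = "channel_schema")
}

#' @export
print.channel_schema <- function(x, ...) {
  cat("<channel_schema>", x$name, "with", length(x$channels), "channels\n")
  invisible(x)
}

#' SBS96 channel labels in COSMIC order
#'
#' @return Character vector of the 96 labels `"X[R>A]Y"`.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(f3 = bases, f5 = bases, sub = subs,
                   stringsAsFactors = FALSE)  # f3 varies fastest, sub slowest
  paste0(g$f5, "[", g$sub, "]", g$f3)
}

#' @rdname channel_schema
#' @export
sbs96_schema <- function() channel_schema("SBS96", sbs96_channels())

schemas_equal <- function(a, b) {
  identical(a$channels, b$channels)
}
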