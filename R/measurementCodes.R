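## Measurement-code grammar for song feature tables.
##
## A code is "<quantity digit 1-9>[<syllable letter a-h>[<note digit>]]":
## the quantity digit indexes one of nine acoustic quantities, an optional
## syllable letter narrows the scope from the whole song to one syllable,
## and an optional trailing digit narrows it further to one note of that
## syllable.  "1b1" is therefore the duration of note 1 of syllable b,
## "2" the peak frequency of the whole song, "8a" the slur direction
## (up/down frequency sweep) of syllable a.

.QUANTITIES <- data.frame(
  digit = 1:9,
  quantity = c("duration_s", "peak_freq_hz", "min_freq_hz", "max_freq_hz",
               "n_repeats", "n_notes", "n_syllables", "slur",
               "proportion_pct"),
  dtype = c("numeric", "numeric", "numeric", "numeric", "numeric",
            "numeric", "numeric", "categorical", "numeric"),
  stringsAsFactors = FALSE
)

#' Parse a song measurement code
#'
#' Decodes a measurement code of the form
#' \code{<quantity digit 1-9>[<syllable letter a-h>[<note digit>]]} into its
#' quantity, scope (song, syllable, or note), optional syllable letter,
#' optional note index, and data type.  The quantity digit is mandatory; the
#' syllable letter is case-insensitive and stored lower-case.  Quantity 8
#' (slur, an up- or down-slurred frequency sweep coded \code{"U"}/\code{"D"})
#' is the single categorical quantity; all others are numeric.
#'
#' @param codes Character vector of measurement codes, e.g.
#'   \code{c("1", "4c", "1b1")}.
#' @return A data.frame with one row per code and columns \code{code},
#'   \code{quantity}, \code{scope}, \code{syllable} (NA when song-scoped),
#'   \code{note_index} (NA unless note-scoped), and \code{dtype}.
#' @examples
#' parseMeasurementCode(c("1b1", "2", "8a"))
#' @export
parseMeasurementCode <- function(codes) {
  if (length(codes) == 0L)
    stop("no measurement codes supplied")
  codes <- as.character(codes)
  m <- regmatches(codes, regexec("^([1-9])([a-hA-H])?([1-9][0-9]*)?$", codes))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad))
    stop("malformed measurement code(s): ",
         paste(sQuote(codes[bad]), collapse = ", "),
         " (expected <quantity digit 1-9>[<syllable a-h>[<note digit>]])")
  digit <- as.integer(vapply(m, `[`, "", 2L))
  syllable <- tolower(vapply(m, `[`, "", 3L))
  note <- vapply(m, `[`, "", 4L)
  out <- data.frame(
    code = paste0(digit, syllable, note),
    quantity = .QUANTITIES$quantity[digit],
    scope = ifelse(syllable == "", "song",
                   ifelse(note == "", "syllable", "note")),
    syllable = ifelse(syllable == "", NA_character_, syllable),
    note_index = ifelse(note == "", NA_integer_, suppressWarnings(as.integer(note))),
    dtype = .QUANTITIES$dtype[digit],
    stringsAsFactors = FALSE
  )
  rownames(out) <- out$code
  out
}

#' Valid slur levels
#'
#' The categorical slur quantity takes exactly two levels: up-slurred
#' (\code{"U"}) and down-slurred (\code{"D"}).
#' @return Character vector \code{c("U", "D")}.
#' @export
slurLevels <- function() c("U", "D")
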