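# Minimal 5x7 bitmap font for burning label text into video frames.
# Each glyph is 7 rows of 5 bits, encoded row-wise as hex (top row first,
# bit 16 = leftmost column). Unknown characters render as blanks; lower
# case maps to upper case.

.font5x7 <- c(
  "A" = "0E11111F111111", "B" = "1E11111E11111E", "C" = "0E111010101 10E",
  "D" = "1E11111111111E", "E" = "1F10101E10101F", "F" = "1F10101E101010",
  "G" = "0E111013111 10F", "H" = "1111111F111111", "I" = "0E0404040404 0E",
  "J" = "070202020212 0C", "K" = "111214181412 11", "L" = "101010101010 1F",
  "M" = "111B1515111111", "N" = "111119151311 11", "O" = "0E111111111 10E",
  "P" = "1E11111E101010", "Q" = "0E111111151 20D", "R" = "1E11111E141211",
  "S" = "0F10100E0101 1E", "T" = "1F040404040404", "U" = "111111111111 0E",
  "V" = "111111111 10A04", "W" = "111111151 51B11", "X" = "11110A040A1111",
  "Y" = "11110A04040404", "Z" = "1F010204081 01F",
  "0" = "0E11131519110E", "1" = "040C040404040E", "2" = "0E110106081 01F",
  "3" = "0E110106011 10E", "4" = "02060A121F0202", "5" = "1F101E010111 0E",
  "6" = "060810 1E11110E", "7" = "1F010204080808", "8" = "0E11110E11110E",
  "9" = "0E11110F01020C", " " = "00000000000000", "-" = "0000001F000000",
  "." = "00000000000C0C", "," = "000000000C0408", ":" = "000C0C000C0C00",
  "'" = "04040800000000", "(" = "02040808080402", ")" = "08040202020408")

.glyph_matrix <- function(ch) {
  hexs <- .font5x7[[toupper(ch)]]
  if (is.null(hexs)) hexs <- .font5x7[[" "]]
  hexs <- gsub(" ", "", hexs, fixed = TRUE)
  rows <- substring(hexs, seq(1, 13, 2), seq(2, 14, 2))
  vals <- strtoi(rows, 16L)
  m <- matrix(0L, 7, 5)
  for (r in 1:7) m[r, ] <- as.integer(bitwAnd(vals[r], c(16L, 8L, 4L, 2L, 1L)) > 0)
  m
}

# Render `text` as a 0/1 matrix, 7 px tall, 6 px advance per character,
# optionally integer-scaled.
.text_bitmap <- function(text, scale = 1L) {
  chars <- strsplit(text, "")[[1]]
  if (!length(chars)) return(matrix(0L, 7L * scale, 0L))
  m <- matrix(0L, 7, 6 * length(chars))
  for (i in seq_along(chars))
    m[, (i - 1) * 6 + 1:5] <- .glyph_matrix(chars[i])
  if (scale > 1L)
    m <- m[rep(seq_len(nrow(m)), each = scale), rep(seq_len(ncol(m)), each = scale)]
  m
}
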