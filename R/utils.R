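#' Length-weighted median
#'
#' Median of values where each value carries a weight (here: base pairs
#' covered by a segment). Equivalent to expanding every value into
#' `weight` unit-length copies and taking the ordinary sample median.
#'
#' @param x Numeric values.
#' @param w Non-negative weights, same length as `x`.
#' @return The weighted median as a single numeric.
#' @examples
#' weightedMedian(c(2, 4), c(9, 1))  # 2
#' @export
weightedMedian <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0), any(w > 0))
  keep <- w > 0 & !is.na(x)
  x <- x[keep]; w <- as.numeric(w[keep])  # bp weights overflow integers
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  half <- sum(w) / 2
  k <- which(cw >= half)[1L]
  if (cw[k] == half && k < length(x)) (x[k] + x[k + 1L]) / 2 else x[k]
}

# Deterministic 32-bit FNV-1a hash of a character scalar; used to stamp a
# configuration fingerprint into output files without a timestamp.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # XOR with a byte only touches the low 8 bits; keep h as a double
    # (it exceeds .Machine$integer.max) and xor the low byte explicitly
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    # multiply by the FNV prime 16777619 = 2^24 + 403, mod 2^32, keeping
    # every intermediate product below 2^53 for exact double arithmetic
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

configHash <- function(config) {
  flat <- unlist(config, use.names = TRUE)
  fnv1a32(paste(names(flat), format(flat, digits = 15), sep = "=", collapse = ";"))
}

# Header comment written at the top of every TSV the package emits.
outputHeader <- function(hash = "none") {
  sprintf("# metCNA %s config=%s",
          as.character(utils::packageVersion("metCNA")), hash)
}

# print numbers with enough significant digits that read-back
# reproduces the double exactly
formatNum <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}
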