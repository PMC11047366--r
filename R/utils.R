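# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
aa_three_to_one <- function(x) {
  out <- suppressWarnings(bio3d::aa321(x))
  out[is.na(out)] <- "X"
  out
}

#' @noRd
aa_one_to_three <- function(x) {
  out <- suppressWarnings(bio3d::aa123(x))
  out[is.na(out)] <- "UNK"
  out
}

# squared-distance matrix between two n x 3 / m x 3 coordinate blocks
#' @noRd
dist2_xyz <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# strip quotes from an mmCIF token
#' @noRd
cif_unquote <- function(x) {
  x <- sub('^"(.*)"$', "\\1", x)
  sub("^'(.*)'$", "\\1", x)
}

# split an mmCIF data line into tokens, honouring single/double quotes
#' @noRd
cif_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1) return(character(0))
  cif_unquote(regmatches(line, list(m))[[1]])
}
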