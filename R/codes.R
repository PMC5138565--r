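# Packed binary hash codes: +1 maps to bit 1, -1 to bit 0; the code inner
# product is computed on packed bytes as r - 2 * popcount(xor).

#' Pack and unpack hash codes
#'
#' A hash code is a length-`r` vector of -1/+1 bits. `pack_code()` stores it
#' one bit per entry (+1 as 1) in a raw vector padded with zero bits to a
#' whole number of bytes, recording `r` as an attribute; `unpack_code()`
#' restores the sign vector exactly.
#'
#' @param bits Numeric vector with entries in `{-1, +1}`.
#' @return `pack_code()`: a raw vector with attribute `r`; `unpack_code()`:
#'   the -1/+1 integer vector.
#' @export
pack_code <- function(bits) {
  if (!all(bits %in% c(-1, 1))) abort("code bits must be -1 or +1")
  r <- length(bits)
  padded <- c(bits > 0, rep(FALSE, (8 - r %% 8) %% 8))
  structure(packBits(padded, type = "raw"), r = r)
}

#' @rdname pack_code
#' @param code A raw vector produced by [pack_code()].
#' @export
unpack_code <- function(code) {
  r <- attr(code, "r")
  if (is.null(r)) abort("packed code is missing its length attribute r")
  bits <- as.integer(rawToBits(code))[seq_len(r)]
  2L * bits - 1L
}

#' Inner product of two hash codes
#'
#' `sum(code_q * code_x)` over the -1/+1 bits, computed on packed codes as
#' `r - 2 * popcount(xor)`; ranges over `[-r, r]` with the parity of `r`.
#' Accepts packed raw codes (from [pack_code()]) or plain -1/+1 vectors.
#'
#' @param code_a,code_b Two codes of equal length.
#' @return Integer inner product.
#' @export
code_inner_product <- function(code_a, code_b) {
  if (is.raw(code_a) && is.raw(code_b)) {
    ra <- attr(code_a, "r")
    rb <- attr(code_b, "r")
    if (is.null(ra) || is.null(rb) || ra != rb || length(code_a) != length(code_b)) {
      abort("code lengths do not match")
    }
    x <- bitwXor(as.integer(code_a), as.integer(code_b))
    return(ra - 2L * sum(popcount_byte[x + 1L]))
  }
  if (length(code_a) != length(code_b)) abort("code lengths do not match")
  as.integer(sum(code_a * code_b))
}

# Pack a +/-1 code matrix (n x r) into an integer byte matrix (nbytes x n)
# for bulk query-time inner products.
pack_code_matrix <- function(B) {
  r <- ncol(B)
  nbytes <- ceiling(r / 8)
  packed <- vapply(seq_len(nrow(B)), function(i) {
    as.integer(unclass(pack_code(B[i, ])))
  }, integer(nbytes))
  m <- matrix(packed, nrow = nbytes)
  attr(m, "r") <- r
  m
}

# Inner products of one packed query byte vector against all columns of a
# packed byte matrix.
code_sims <- function(packed_matrix, q_bytes, r) {
  x <- bitwXor(packed_matrix, as.integer(q_bytes))
  r - 2L * colSums(matrix(popcount_byte[x + 1L], nrow = nrow(packed_matrix)))
}
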