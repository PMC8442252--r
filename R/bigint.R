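# Minimal exact signed integers of arbitrary size, used only by the
# labeled-DAG count recurrence, which overflows doubles at ten variables.
# Representation: list(sign = -1L/0L/1L, mag = double vector of base-10000
# limbs, little-endian, no trailing zero limbs).  Only the operations the
# recurrence needs exist: add, subtract, multiply, powers of two, binomials.
# Limb products are < 1e8 and convolution sums stay far below 2^53, so plain
# doubles hold every intermediate exactly.

.BI_BASE <- 10000

bi_zero <- function() structure(list(sign = 0L, mag = 0), class = "pm_bigint")

bi <- function(x) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x))
    pm_stop("bigint literal must be a single integer-valued number")
  sign <- if (x > 0) 1L else if (x < 0) -1L else 0L
  x <- abs(x)
  if (x >= 2^53) pm_stop("bigint literal too large to be exact as a double")
  if (sign == 0L) return(bi_zero())
  mag <- numeric(0)
  while (x > 0) {
    mag <- c(mag, x %% .BI_BASE)
    x <- x %/% .BI_BASE
  }
  structure(list(sign = sign, mag = mag), class = "pm_bigint")
}

bi_trim <- function(mag) {
  n <- length(mag)
  while (n > 1L && mag[n] == 0) n <- n - 1L
  mag[seq_len(n)]
}

bi_carry <- function(mag) {
  i <- 1L
  while (i <= length(mag)) {
    if (mag[i] >= .BI_BASE) {
      q <- mag[i] %/% .BI_BASE
      mag[i] <- mag[i] - q * .BI_BASE
      if (i == length(mag)) mag <- c(mag, 0)
      mag[i + 1L] <- mag[i + 1L] + q
    }
    i <- i + 1L
  }
  bi_trim(mag)
}

# magnitude comparison: -1, 0, 1
bi_cmp_mag <- function(a, b) {
  if (length(a) != length(b)) return(if (length(a) < length(b)) -1L else 1L)
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(if (a[i] < b[i]) -1L else 1L)
  }
  0L
}

bi_add_mag <- function(a, b) {
  n <- max(length(a), length(b))
  out <- numeric(n)
  out[seq_along(a)] <- a
  out[seq_along(b)] <- out[seq_along(b)] + b
  bi_carry(out)
}

# requires |a| >= |b|
bi_sub_mag <- function(a, b) {
  out <- a
  out[seq_along(b)] <- out[seq_along(b)] - b
  i <- 1L
  while (i < length(out)) {
    if (out[i] < 0) {
      out[i] <- out[i] + .BI_BASE
      out[i + 1L] <- out[i + 1L] - 1
    }
    i <- i + 1L
  }
  bi_trim(out)
}

bi_neg <- function(a) {
  a$sign <- -a$sign
  a
}

bi_add <- function(a, b) {
  if (a$sign == 0L) return(b)
  if (b$sign == 0L) return(a)
  if (a$sign == b$sign) {
    return(structure(list(sign = a$sign, mag = bi_add_mag(a$mag, b$mag)),
                     class = "pm_bigint"))
  }
  cmp <- bi_cmp_mag(a$mag, b$mag)
  if (cmp == 0L) return(bi_zero())
  if (cmp > 0L) {
    structure(list(sign = a$sign, mag = bi_sub_mag(a$mag, b$mag)),
              class = "pm_bigint")
  } else {
    structure(list(sign = b$sign, mag = bi_sub_mag(b$mag, a$mag)),
              class = "pm_bigint")
  }
}

bi_sub <- function(a, b) bi_add(a, bi_neg(b))

bi_mul <- function(a, b) {
  if (a$sign == 0L || b$sign == 0L) return(bi_zero())
  la <- length(a$mag)
  lb <- length(b$mag)
  out <- numeric(la + lb)
  for (i in seq_len(la)) {
    out[i:(i + lb - 1L)] <- out[i:(i + lb - 1L)] + a$mag[i] * b$mag
    # normalize eagerly so convolution sums cannot approach 2^53
    if (i %% 64L == 0L) out <- c(bi_carry(out), numeric(la + lb))[seq_len(la + lb)]
  }
  structure(list(sign = a$sign * b$sign, mag = bi_carry(out)),
            class = "pm_bigint")
}

bi_pow2 <- function(e) {
  pm_check_count(e, "e")
  out <- bi(1)
  two <- bi(2)
  if (e == 0) return(out)
  # square-and-multiply on the exponent's bits
  bits <- integer(0)
  n <- e
  while (n > 0) {
    bits <- c(bits, n %% 2)
    n <- n %/% 2
  }
  base <- two
  for (i in seq_along(bits)) {
    if (bits[i] == 1) out <- bi_mul(out, base)
    if (i < length(bits)) base <- bi_mul(base, base)
  }
  out
}

# exact binomial coefficients via Pascal's rule (addition only)
bi_binom <- function(n, k) {
  if (k < 0 || k > n) return(bi_zero())
  row <- list(bi(1))
  if (n == 0) return(row[[1L]])
  for (m in seq_len(n)) {
    new <- vector("list", m + 1L)
    new[[1L]] <- bi(1)
    new[[m + 1L]] <- bi(1)
    if (m > 1L) {
      for (j in 2:m) new[[j]] <- bi_add(row[[j - 1L]], row[[j]])
    }
    row <- new
  }
  row[[k + 1L]]
}

bi_to_character <- function(a) {
  if (a$sign == 0L) return("0")
  digits <- rev(vapply(a$mag, function(d) sprintf("%04d", d), character(1)))
  digits[1L] <- sub("^0+", "", digits[1L])
  paste0(if (a$sign < 0L) "-" else "", paste(digits, collapse = ""))
}

# exact double if representable, NA otherwise
bi_to_double <- function(a) {
  if (length(a$mag) > 4L) {
    # > 16 decimal digits; check against 2^53 explicitly
    s <- bi_to_character(a)
    if (nchar(sub("^-", "", s)) > 16L) return(NA_real_)
  }
  val <- 0
  for (i in rev(seq_along(a$mag))) val <- val * .BI_BASE + a$mag[i]
  if (val >= 2^53) return(NA_real_)
  a$sign * val
}
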