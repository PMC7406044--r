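# Exact big-integer arithmetic for block-set counts.
#
# Designs of realistic size overflow doubles (a 64-unit, 4x16 design has
# ~1e34 unique block sets), and no arbitrary-precision integer package is a
# dependency, so counts are built exactly from the prime factorization of
# the factorial ratio: digits are stored little-endian in base 1e7 (every
# intermediate product stays well below 2^53).

BIG_BASE <- 1e7

big_from_int <- function(x) {
  stopifnot(x >= 0, x < BIG_BASE)
  as.double(x)
}

big_mul_small <- function(digits, m) {
  # m must satisfy digit * m + carry < 2^53; true for m <= ~9e8
  out <- digits * m
  carry <- 0
  for (i in seq_along(out)) {
    v <- out[i] + carry
    carry <- floor(v / BIG_BASE)
    out[i] <- v - carry * BIG_BASE
  }
  while (carry > 0) {
    out <- c(out, carry %% BIG_BASE)
    carry <- floor(carry / BIG_BASE)
  }
  out
}

big_to_string <- function(digits) {
  n <- length(digits)
  head <- format(digits[n], scientific = FALSE)
  if (n == 1L) return(head)
  rest <- sprintf("%07d", rev(digits[-n]))
  paste0(head, paste(rest, collapse = ""))
}

big_to_double <- function(digits) {
  sum(digits * BIG_BASE^(seq_along(digits) - 1))
}

# exponent of prime p in n! (Legendre's formula)
legendre_exponent <- function(n, p) {
  e <- 0
  q <- p
  while (q <= n) {
    e <- e + n %/% q
    q <- q * p
  }
  e
}

primes_up_to <- function(n) {
  if (n < 2) return(integer(0))
  sieve <- rep(TRUE, n)
  sieve[1] <- FALSE
  i <- 2L
  while (i * i <= n) {
    if (sieve[i]) sieve[seq.int(i * i, n, by = i)] <- FALSE
    i <- i + 1L
  }
  which(sieve)
}

# exact n! / (prod(divisor_factorials)!) as big digits; the ratio must be an
# integer (guaranteed for multinomial-type counts)
big_factorial_ratio <- function(n, divisor_factorials) {
  digits <- big_from_int(1)
  for (p in primes_up_to(max(n, 1))) {
    e <- legendre_exponent(n, p) -
      sum(vapply(divisor_factorials, legendre_exponent, 0, p = p))
    if (e < 0) stop("internal error: non-integer factorial ratio")
    while (e > 0) {
      # multiply by the largest power of p that fits a digit
      chunk <- p
      used <- 1
      while (used + 1 <= e && chunk * p < BIG_BASE) {
        chunk <- chunk * p
        used <- used + 1
      }
      digits <- big_mul_small(digits, chunk)
      e <- e - used
    }
  }
  digits
}

#' Count the unique block sets of a design exactly
#'
#' The number of distinct ways to divide `n_units` labeled units into blocks
#' of the given sizes is the multinomial coefficient
#' `n! / (b_1! ... b_k! r!)` (with `r` the leftover count), divided by
#' `m_s!` for every group of `m_s` equal-size blocks, because blocks of the
#' same size are unlabeled and interchangeable. The leftover pool is *not*
#' interchangeable with a block of equal size. For 16 units in two blocks of
#' 8 this gives `C(16,8)/2 = 6435`.
#'
#' The count is computed in exact arbitrary-precision integer arithmetic, so
#' designs far beyond double precision (e.g. 64 units in four blocks of 16,
#' ~2.8e34 sets) are counted exactly.
#'
#' @param n_units Number of experimental units in the cohort.
#' @param block_sizes Positive integers; must sum to at most `n_units`.
#' @return An object of class `blockset_count`: the exact integer, printable
#'   in full or in scientific form, convertible with `as.numeric()` and
#'   `format()`.
#' @examples
#' count_unique_block_sets(16, c(8, 8)) # 6435
#' format(count_unique_block_sets(64, rep(16, 4)), type = "scientific")
#' @export
count_unique_block_sets <- function(n_units, block_sizes) {
  n_units <- as.integer(n_units)
  block_sizes <- as.integer(block_sizes)
  if (n_units < 1L || any(block_sizes < 1L)) {
    stop("n_units and block_sizes must be positive", call. = FALSE)
  }
  if (sum(block_sizes) > n_units) {
    stop(sprintf("block sizes sum to %d but there are only %d units",
                 sum(block_sizes), n_units), call. = FALSE)
  }
  leftover <- n_units - sum(block_sizes)
  multiplicities <- table(block_sizes)
  digits <- big_factorial_ratio(
    n_units, c(block_sizes, leftover, as.integer(multiplicities)))
  structure(list(digits = digits,
                 string = big_to_string(digits),
                 n_units = n_units,
                 block_sizes = block_sizes),
            class = "blockset_count")
}

#' @export
as.numeric.blockset_count <- function(x, ...) big_to_double(x$digits)

#' @export
as.double.blockset_count <- function(x, ...) big_to_double(x$digits)

#' Format an exact block-set count
#'
#' @param x A [count_unique_block_sets()] result.
#' @param type `"exact"` for the full decimal integer, `"scientific"` for a
#'   rounded mantissa-exponent form.
#' @param sig_digits Significant digits of the scientific form (default 2);
#'   rounding is round-half-to-even.
#' @param ... Unused.
#' @export
format.blockset_count <- function(x, type = c("exact", "scientific"),
                                  sig_digits = 2, ...) {
  type <- match.arg(type)
  if (type == "exact") return(x$string)
  s <- x$string
  exponent <- nchar(s) - 1L
  digits <- as.integer(strsplit(s, "")[[1]])
  mant <- round_half_even_digits(digits, sig_digits)
  if (mant$overflow) exponent <- exponent + 1L
  mantissa <- mant$digits
  out <- if (sig_digits > 1) {
    paste0(mantissa[1], ".", paste(mantissa[-1], collapse = ""))
  } else {
    as.character(mantissa[1])
  }
  paste0(out, "e", exponent)
}

# round a decimal digit vector to `sig` significant digits, half-to-even
round_half_even_digits <- function(digits, sig) {
  if (length(digits) <= sig) {
    return(list(digits = c(digits, rep(0L, sig - length(digits))),
                overflow = FALSE))
  }
  kept <- digits[seq_len(sig)]
  tail <- digits[-seq_len(sig)]
  round_up <- if (tail[1] > 5L) {
    TRUE
  } else if (tail[1] < 5L) {
    FALSE
  } else if (any(tail[-1] > 0L)) {
    TRUE
  } else {
    kept[sig] %% 2L == 1L  # exact half: round to even
  }
  overflow <- FALSE
  if (round_up) {
    i <- sig
    repeat {
      kept[i] <- kept[i] + 1L
      if (kept[i] < 10L) break
      kept[i] <- 0L
      i <- i - 1L
      if (i == 0L) {
        kept <- c(1L, kept)[seq_len(sig)]
        overflow <- TRUE
        break
      }
    }
  }
  list(digits = kept, overflow = overflow)
}

#' @export
print.blockset_count <- function(x, ...) {
  cat(sprintf("Unique block sets for %d units in blocks of (%s): %s (%s)\n",
              x$n_units, paste(x$block_sizes, collapse = ", "),
              x$string, format(x, type = "scientific")))
  invisible(x)
}

#' Probability that a partial search misses all top-k block sets
#'
#' When `sampled` distinct block sets are drawn uniformly without
#' replacement from the `total` unique sets of a design, the probability
#' that none of a designated best `k` is among them is hypergeometric:
#' `C(total - k, sampled) / C(total, sampled)`, evaluated as the exact
#' product `prod((total - sampled - i) / (total - i))` for `i = 0..k-1`.
#'
#' For the 16-unit, two-blocks-of-8 design (6435 unique sets), searching
#' half of them leaves under a 0.1% chance of missing every one of the ten
#' best-balanced block sets.
#'
#' @param total Total number of unique block sets (a number or a
#'   [count_unique_block_sets()] result).
#' @param sampled Number of distinct block sets examined, `0 <= sampled <=
#'   total`.
#' @param k Size of the designated top set, `0 <= k <= total`.
#' @return The miss probability in `[0, 1]`.
#' @examples
#' top_k_miss_probability(6435, 3218, 10) # ~9.7e-4
#' @export
top_k_miss_probability <- function(total, sampled, k) {
  if (inherits(total, "blockset_count")) total <- as.numeric(total)
  if (length(total) != 1L || length(sampled) != 1L || length(k) != 1L ||
      is.na(total) || is.na(sampled) || is.na(k)) {
    stop("total, sampled and k must be single numbers", call. = FALSE)
  }
  if (sampled < 0 || sampled > total) {
    stop("sampled must satisfy 0 <= sampled <= total", call. = FALSE)
  }
  if (k < 0 || k > total) {
    stop("k must satisfy 0 <= k <= total", call. = FALSE)
  }
  if (k == 0) return(1)
  if (sampled == 0) return(1)
  if (sampled > total - k) return(0)
  i <- seq_len(k) - 1
  prod((total - sampled - i) / (total - i))
}
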