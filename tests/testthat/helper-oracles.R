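# Independent reference implementations used to check the package's
# optimised code paths on small inputs. Deliberately brute-force and
# structurally unlike the implementations they check.

oracle_revcomp_chars <- function(v) {
  rev(c(A = "T", C = "G", G = "C", T = "A")[v])
}

# All-pairs self-mapping coverage: every length-L window of both strands
# is a read; every offset x strand is a placement; a (read, placement)
# pair matches at Hamming distance <= mm and then covers the L genome
# positions under the placement.
oracle_selfmap <- function(seq_string, L, mm, circular = FALSE) {
  g <- strsplit(seq_string, "", fixed = TRUE)[[1L]]
  n <- length(g)
  n_off <- if (circular) n else n - L + 1L
  cov <- integer(n)
  if (n_off <= 0L) return(cov)
  idx <- function(j) ((j - 1L + seq_len(L) - 1L) %% n) + 1L
  W <- t(vapply(seq_len(n_off), function(j) g[idx(j)], character(L)))
  R <- t(apply(W, 1L, oracle_revcomp_chars))
  X <- rbind(W, R)  # all reads
  for (j in seq_len(n_off)) {
    d_fwd <- rowSums(X != matrix(W[j, ], nrow(X), L, byrow = TRUE))
    d_rev <- rowSums(X != matrix(R[j, ], nrow(X), L, byrow = TRUE))
    placements <- sum(d_fwd <= mm) + sum(d_rev <= mm)
    cov[idx(j)] <- cov[idx(j)] + placements
  }
  cov
}

# Scalar rule-by-rule reclassification of one site for every focal line.
# counts: named list per line of c(A=,C=,G=,T=).
oracle_classify_site <- function(ref, counts, unique_flag, line_means,
                                 params) {
  lines <- names(counts)
  maj <- lapply(counts, function(ct) {
    d <- sum(ct)
    if (d == 0) return(list(base = NA, agree = 0, depth = 0))
    mx <- max(ct)
    if (sum(ct == mx) > 1 || mx / d < 0.5)
      return(list(base = NA, agree = 0, depth = d))
    list(base = names(ct)[which.max(ct)], agree = mx / d, depth = d)
  })
  depths <- vapply(maj, `[[`, 0, "depth")
  res <- list()
  for (l in lines) {
    o <- NULL
    if (params$require_unique && !unique_flag) {
      o <- c("EXCLUDED", "not_unique")
    } else if (any(depths == 0)) {
      o <- c("EXCLUDED", "not_covered_all_lines")
    } else {
      m <- maj[[l]]
      if (m$depth < params$min_cov_focal) o <- c("EXCLUDED", "low_coverage")
      else if (m$depth > params$max_cov_factor * line_means[[l]])
        o <- c("EXCLUDED", "high_coverage")
      else if (is.na(m$base)) o <- c("EXCLUDED", "tie_no_call")
      else if (m$agree < params$min_agree_focal)
        o <- c("EXCLUDED", "low_agreement")
      else {
        others <- setdiff(lines, l)
        weak <- vapply(others, function(ol) {
          om <- maj[[ol]]
          if (om$depth >= params$min_cov_confirm && !is.na(om$base) &&
              om$agree >= params$min_agree_confirm) om$base else NA_character_
        }, "")
        if (m$base != ref) {
          if (any(!is.na(weak) & weak == m$base))
            o <- c("EXCLUDED", "shared_candidate")
          else if (isTRUE(params$strict_confirm) &&
                   !all(!is.na(weak) & weak == ref))
            o <- c("EXCLUDED", "confirmation_failed")
          else o <- c("MUTATION", NA)
        } else {
          if (all(!is.na(weak) & weak == ref)) o <- c("UNCHANGED", NA)
          else o <- c("EXCLUDED", "confirmation_failed")
        }
      }
    }
    res[[l]] <- o
  }
  res
}

# direct summation of the binomial upper tail P[X > thresh]
oracle_binom_tail <- function(thresh, size, p) {
  ks <- seq.int(floor(thresh) + 1L, size)
  if (length(ks) == 0L) return(0)
  sum(stats::dbinom(ks, size, p))
}

# Poisson interval bounds by numerical inversion of the Poisson CDF
oracle_poisson_bounds <- function(k, level = 0.95) {
  alpha <- 1 - level
  lower <- if (k == 0) 0 else
    stats::uniroot(function(l) stats::ppois(k - 1, l, lower.tail = FALSE) -
                     alpha / 2, c(1e-12, 10 * k + 10), tol = 1e-10)$root
  upper <- stats::uniroot(function(l) stats::ppois(k, l) - alpha / 2,
                          c(1e-12, 10 * k + 50), tol = 1e-10)$root
  c(lower = lower, upper = upper)
}
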