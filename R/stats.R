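#' Two-way fully within-subject ANOVA with Greenhouse–Geisser correction
#'
#' Partitions the sums of squares of a subjects x A x B design with one
#' observation per cell into effects A, B, A:B with error strata A:S, B:S,
#' A:B:S. Each within effect's F is tested at Greenhouse–Geisser-corrected
#' degrees of freedom (epsilon from the covariance of orthonormalized
#' contrast scores; applied unconditionally, which is conservative when
#' sphericity holds). Effect sizes are generalized eta squared,
#' \eqn{\eta_g^2 = SS_{effect} / (SS_{effect} + SS_{subjects} + \sum SS_{error})}.
#'
#' @param data data.frame in long format.
#' @param dv Name of the numeric response column (default "value").
#' @param within Length-2 character: the two within-subject factor columns
#'   (A, B), default `c("test", "scenario")`.
#' @param subject Name of the subject-id column (default "subject").
#' @return data.frame with one row per effect (`A`, `B`, `A:B`): `effect`,
#'   `df1`, `df2` (uncorrected), `epsilon`, `df1_corr`, `df2_corr`, `F`,
#'   `p` (G-G corrected), `eta_g2`, `SS`, `SS_error`, `degenerate`.
#' @export
rm_anova_2way <- function(data, dv = "value", within = c("test", "scenario"),
                          subject = "subject") {
  stopifnot(all(c(dv, within, subject) %in% names(data)))
  A <- factor(data[[within[1]]])
  B <- factor(data[[within[2]]])
  S <- factor(data[[subject]])
  y <- data[[dv]]
  a <- nlevels(A); b <- nlevels(B); n <- nlevels(S)
  if (n < 3) stop("need at least 3 subjects")
  counts <- table(S, A, B)
  if (any(counts != 1)) {
    bad <- which(counts != 1, arr.ind = TRUE)
    stop("design must have exactly one observation per subject x cell; offending cells: ",
         paste(apply(bad, 1, function(r) {
           paste(dimnames(counts)[[1]][r[1]], dimnames(counts)[[2]][r[2]],
                 dimnames(counts)[[3]][r[3]], sep = "/")
         }), collapse = ", "))
  }

  # subjects x (a*b) response matrix, A-major / B-minor column order
  Y <- matrix(NA_real_, n, a * b)
  col_of <- (as.integer(A) - 1L) * b + as.integer(B)
  Y[cbind(as.integer(S), col_of)] <- y

  if (a == 1L && b == 1L) stop("both factors have a single level")
  if (a == 1L || b == 1L) {
    # one-way reduction: the multi-level factor is tested against its
    # subject interaction, the single-level factor contributes nothing
    k <- max(a, b)
    lev <- if (a > 1) A else B
    M <- matrix(NA_real_, n, k)
    M[cbind(as.integer(S), as.integer(lev))] <- y
    g <- mean(M)
    m_s <- rowMeans(M)
    m_k <- colMeans(M)
    SS_S <- k * sum((m_s - g)^2)
    SS_K <- n * sum((m_k - g)^2)
    SS_tot <- sum((M - g)^2)
    SS_KS <- SS_tot - SS_S - SS_K
    eps <- gg_epsilon(M %*% orthonormal_contrasts(k))
    df1 <- k - 1; df2 <- (k - 1) * (n - 1)
    tol <- 1e-12 * max(SS_tot, 1)
    degen <- SS_KS <= tol && SS_K > tol
    Fv <- if (degen) NA_real_ else if (SS_K <= tol && SS_KS <= tol) 0 else
      (SS_K / df1) / (SS_KS / df2)
    p <- if (is.na(Fv)) NA_real_ else if (Fv == 0 && SS_KS <= tol) 1 else
      stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
    eta <- if (SS_K + SS_S + SS_KS <= 0) 0 else SS_K / (SS_K + SS_S + SS_KS)
    out <- data.frame(effect = if (a > 1) "A" else "B",
                      df1 = df1, df2 = df2, epsilon = eps,
                      df1_corr = df1 * eps, df2_corr = df2 * eps,
                      F = Fv, p = p, eta_g2 = eta, SS = SS_K,
                      SS_error = SS_KS, degenerate = degen,
                      stringsAsFactors = FALSE)
    attr(out, "SS_subject") <- SS_S
    attr(out, "SS_total") <- SS_tot
    attr(out, "factors") <- stats::setNames(within, c("A", "B"))
    return(out)
  }

  g <- mean(Y)
  m_s <- rowMeans(Y)                                     # subject means
  M_A <- t(vapply(seq_len(n), function(i)                # subject x A means
    tapply(Y[i, ], rep(seq_len(a), each = b), mean), numeric(a)))
  M_B <- t(vapply(seq_len(n), function(i)                # subject x B means
    tapply(Y[i, ], rep(seq_len(b), times = a), mean), numeric(b)))
  m_a <- colMeans(M_A); m_b <- colMeans(M_B)
  m_ab <- matrix(colMeans(Y), a, b, byrow = TRUE)        # cell means, A rows

  SS_S  <- a * b * sum((m_s - g)^2)
  SS_A  <- n * b * sum((m_a - g)^2)
  SS_B  <- n * a * sum((m_b - g)^2)
  SS_AB <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + g)^2)
  SS_AS <- b * sum((M_A - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + g)^2)
  SS_BS <- a * sum((M_B - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + g)^2)
  SS_tot <- sum((Y - g)^2)
  SS_ABS <- SS_tot - SS_S - SS_A - SS_B - SS_AB - SS_AS - SS_BS

  Ca <- orthonormal_contrasts(a)
  Cb <- orthonormal_contrasts(b)
  eps_A  <- gg_epsilon(M_A %*% Ca)
  eps_B  <- gg_epsilon(M_B %*% Cb)
  eps_AB <- gg_epsilon(Y %*% kronecker(Ca, Cb))

  eff <- function(name, SS_e, df1, SS_err, df2, eps) {
    tol <- 1e-12 * max(SS_tot, 1)
    if (SS_e <= tol && SS_err <= tol) {
      # no effect and no error variance (e.g. constant data): F = 0
      degen <- FALSE; Fv <- 0; p <- 1
    } else if (SS_err <= tol) {
      degen <- TRUE; Fv <- NA_real_; p <- NA_real_
    } else {
      degen <- FALSE
      Fv <- (SS_e / df1) / (SS_err / df2)
      p <- stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
    }
    denom_eta <- SS_e + SS_S + SS_AS + SS_BS + SS_ABS
    eta <- if (denom_eta <= 0) 0 else SS_e / denom_eta
    data.frame(effect = name, df1 = df1, df2 = df2, epsilon = eps,
               df1_corr = df1 * eps, df2_corr = df2 * eps,
               F = Fv, p = p, eta_g2 = eta, SS = SS_e, SS_error = SS_err,
               degenerate = degen, stringsAsFactors = FALSE)
  }
  out <- rbind(
    eff("A",   SS_A,  a - 1,           SS_AS,  (a - 1) * (n - 1),           eps_A),
    eff("B",   SS_B,  b - 1,           SS_BS,  (b - 1) * (n - 1),           eps_B),
    eff("A:B", SS_AB, (a - 1) * (b - 1), SS_ABS, (a - 1) * (b - 1) * (n - 1), eps_AB)
  )
  attr(out, "SS_subject") <- SS_S
  attr(out, "SS_total") <- SS_tot
  attr(out, "factors") <- stats::setNames(within, c("A", "B"))
  out
}

# k x (k-1) orthonormal basis of the contrast space (orthogonal to the
# constant), via QR of Helmert contrasts
orthonormal_contrasts <- function(k) {
  if (k < 2) stop("factor needs at least 2 levels")
  qr.Q(qr(stats::contr.helmert(k)))
}

# Greenhouse-Geisser epsilon from n x d orthonormal contrast scores:
# eps = tr(Sigma)^2 / (d * tr(Sigma^2)), bounded to [1/d, 1]
gg_epsilon <- function(Z) {
  d <- ncol(Z)
  if (d == 1L) return(1)
  Sg <- stats::cov(Z)
  tr <- sum(diag(Sg))
  denom <- d * sum(Sg * Sg)
  if (denom <= 0) return(1)
  min(1, max(1 / d, tr^2 / denom))
}

#' Bonferroni-corrected paired t-tests between design cells
#'
#' Runs a paired t-test for each requested pair of (A, B) cells and
#' Bonferroni-corrects the p values by `family_size`. Comparisons with zero
#' difference variance but a non-zero mean difference are flagged degenerate
#' rather than reported with an infinite t.
#'
#' @param data Long-format data.frame as in [rm_anova_2way()].
#' @param comparisons List of comparisons; each is a list of two cells, a
#'   cell being a character vector `c(A_level, B_level)`.
#' @param family_size Bonferroni divisor (defaults to the number of
#'   comparisons).
#' @param dv,within,subject Column names as in [rm_anova_2way()].
#' @return data.frame with one row per comparison: cell labels, `n`, `t`,
#'   `df`, `p_raw`, `p_corrected`, `degenerate`.
#' @export
posthoc_paired <- function(data, comparisons, family_size = length(comparisons),
                           dv = "value", within = c("test", "scenario"),
                           subject = "subject") {
  cell_values <- function(cell) {
    sel <- data[[within[1]]] == cell[1] & data[[within[2]]] == cell[2]
    v <- data[sel, ]
    stats::setNames(v[[dv]], v[[subject]])
  }
  rows <- lapply(comparisons, function(cmp) {
    v1 <- cell_values(cmp[[1]])
    v2 <- cell_values(cmp[[2]])
    subj <- intersect(names(v1), names(v2))
    if (length(subj) < 3) stop("fewer than 3 paired observations for comparison ",
                               paste(unlist(cmp), collapse = " vs "))
    d <- v1[subj] - v2[subj]
    degenerate <- FALSE
    if (stats::sd(d) == 0) {
      if (all(d == 0)) {
        tval <- 0; p <- 1
      } else {
        tval <- NA_real_; p <- NA_real_; degenerate <- TRUE
      }
      df <- length(d) - 1
    } else {
      tt <- stats::t.test(v1[subj], v2[subj], paired = TRUE)
      tval <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
    }
    data.frame(cell1 = paste(cmp[[1]], collapse = "."),
               cell2 = paste(cmp[[2]], collapse = "."),
               n = length(subj), t = tval, df = df, p_raw = p,
               p_corrected = if (is.na(p)) NA_real_ else min(1, p * family_size),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mass-univariate repeated-measures ANOVA over units
#'
#' Runs [rm_anova_2way()] once per unit (channel pair or channel) and flags
#' units whose p value for the target effect falls below alpha divided by
#' the number of units — the Bonferroni divisor is 276 for the 24-channel
#' pair-level analysis and 24 at the channel level. Units with degenerate
#' (zero-variance) error strata are skipped with a message.
#'
#' @param data Long-format data.frame with an additional `unit` column.
#' @param effect Which effect's p value to threshold: "A", "B" or "A:B"
#'   (default "A:B", the interaction).
#' @param alpha Family-wise level (default 0.05).
#' @param unit Name of the unit column.
#' @param dv,within,subject Column names as in [rm_anova_2way()].
#' @return data.frame with one row per unit x effect, plus columns
#'   `unit`, `divisor`, `significant` (for the target effect's rows).
#' @export
mass_univariate <- function(data, effect = "A:B", alpha = 0.05,
                            unit = "unit", dv = "value",
                            within = c("test", "scenario"),
                            subject = "subject") {
  stopifnot(unit %in% names(data))
  units <- unique(data[[unit]])
  divisor <- length(units)
  res <- lapply(units, function(u) {
    sub <- data[data[[unit]] == u, ]
    r <- tryCatch(rm_anova_2way(sub, dv = dv, within = within, subject = subject),
                  error = function(e) NULL)
    if (is.null(r)) {
      message("mass_univariate: unit ", u, " skipped (ANOVA failed)")
      return(NULL)
    }
    if (any(r$degenerate)) {
      message("mass_univariate: unit ", u, " skipped (zero-variance error stratum)")
      return(NULL)
    }
    r[[unit]] <- u
    r
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res)) stop("no testable units")
  res$divisor <- divisor
  res$significant <- res$effect == effect & !is.na(res$p) & res$p < alpha / divisor
  attr(res, "divisor") <- divisor
  res
}

#' Collapse trial-level values to condition means
#'
#' Averages all trials of a (subject, test, scenario) cell, the score taken
#' as that cell's performance.
#'
#' @param data Trial-level data.frame with subject/test/scenario columns and
#'   a numeric response.
#' @param dv,within,subject Column names as in [rm_anova_2way()].
#' @return Long-format data.frame with one row per subject x cell.
#' @export
condition_average <- function(data, dv = "value",
                              within = c("test", "scenario"),
                              subject = "subject") {
  stopifnot(all(c(dv, within, subject) %in% names(data)))
  f <- interaction(data[[subject]], data[[within[1]]], data[[within[2]]],
                   drop = TRUE)
  if (any(table(data[[subject]], data[[within[1]]], data[[within[2]]]) == 0)) {
    stop("empty (subject, cell) combination")
  }
  agg <- stats::aggregate(data[[dv]],
                          by = list(data[[subject]], data[[within[1]]],
                                    data[[within[2]]]),
                          FUN = mean)
  names(agg) <- c(subject, within, dv)
  agg
}
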