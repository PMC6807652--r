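#' Two-way (2 x 4) repeated-measures ANOVA
#'
#' Classical within-subject decomposition by sums of squares for one
#' fully-crossed cell of a metric panel: factors condition (RW, SR) and
#' time of day (T1000..T2200), both within subject, one observation per
#' subject x condition x time. Each effect is tested against its own
#' subject-by-effect interaction:
#' `F_condition = MS_C / MS_CxS` on (1, n-1) df,
#' `F_time = MS_T / MS_TxS` on (3, 3(n-1)) df,
#' `F_interaction = MS_CT / MS_CTxS` on (3, 3(n-1)) df.
#' An optional Greenhouse-Geisser correction (off by default, matching
#' the uncorrected convention) multiplies the df of the time and
#' interaction tests by the epsilon estimated from the within-subject
#' covariance of the effect's orthonormal contrasts.
#'
#' @param values numeric vector of observations.
#' @param subject,condition,session parallel factor vectors; every
#'   subject must have all 8 condition x session cells exactly once, and
#'   at least 3 subjects are required.
#' @param ggCorrection apply Greenhouse-Geisser df correction to the
#'   time and interaction tests.
#' @return data.frame with one row: F, df pairs and p for the three
#'   effects.
#' @examples
#' cfg <- expand.grid(subject = paste0("S", 1:6),
#'                    condition = c("RW", "SR"),
#'                    session = c("T1000", "T1400", "T1800", "T2200"))
#' y <- rnorm(nrow(cfg)) + 0.8 * (cfg$condition == "SR")
#' rmAnova(y, cfg$subject, cfg$condition, cfg$session)
#' @export
rmAnova <- function(values, subject, condition, session,
                    ggCorrection = FALSE) {
  subject <- as.character(subject)
  condition <- as.character(condition)
  session <- as.character(session)
  subj_lv <- unique(subject)
  s <- length(subj_lv)
  if (s < 3L) stop("at least 3 subjects are required")
  cond_lv <- sort(unique(condition))
  sess_lv <- sort(unique(session))
  a <- length(cond_lv); b <- length(sess_lv)
  key <- paste(subject, condition, session, sep = "/")
  full <- as.vector(outer(outer(subj_lv, cond_lv, paste, sep = "/"),
                          sess_lv, paste, sep = "/"))
  missing <- setdiff(full, key)
  if (length(missing) || anyDuplicated(key))
    stop("design is not complete and balanced; missing or duplicated cells: ",
         paste(c(missing, unique(key[duplicated(key)])), collapse = ", "))
  if (anyNA(values)) stop("values contain NA")

  # y as subject x condition x session array
  y <- array(NA_real_, c(s, a, b))
  y[cbind(match(subject, subj_lv), match(condition, cond_lv),
          match(session, sess_lv))] <- values
  gm <- mean(y)
  m_s <- apply(y, 1L, mean); m_a <- apply(y, 2L, mean)
  m_b <- apply(y, 3L, mean)
  m_sa <- apply(y, c(1L, 2L), mean); m_sb <- apply(y, c(1L, 3L), mean)
  m_ab <- apply(y, c(2L, 3L), mean)

  ss_a <- s * b * sum((m_a - gm)^2)
  ss_b <- s * a * sum((m_b - gm)^2)
  ss_ab <- s * sum((sweep(sweep(m_ab, 1L, m_a), 2L, m_b) + gm)^2)
  ss_as <- b * sum((sweep(sweep(m_sa, 1L, m_s), 2L, m_a) + gm)^2)
  ss_bs <- a * sum((sweep(sweep(m_sb, 1L, m_s), 2L, m_b) + gm)^2)
  resid <- y
  for (i in seq_len(s)) for (j in seq_len(a)) for (k in seq_len(b))
    resid[i, j, k] <- y[i, j, k] - m_sa[i, j] - m_sb[i, k] - m_ab[j, k] +
      m_s[i] + m_a[j] + m_b[k] - gm
  ss_abs <- sum(resid^2)

  df_a <- a - 1; df_b <- b - 1; df_ab <- df_a * df_b
  df_as <- df_a * (s - 1); df_bs <- df_b * (s - 1)
  df_abs <- df_ab * (s - 1)
  if (ss_as <= 0 || ss_bs <= 0 || ss_abs <= 0)
    stop("zero error variance: F statistics are undefined for this cell")

  f_a <- (ss_a / df_a) / (ss_as / df_as)
  f_b <- (ss_b / df_b) / (ss_bs / df_bs)
  f_ab <- (ss_ab / df_ab) / (ss_abs / df_abs)

  eps_b <- eps_ab <- 1
  if (ggCorrection) {
    eps_b <- .gg_epsilon(matrix(m_sb, s, b))
    if (a == 2L) {
      # interaction scores: per subject, the condition-difference
      # profile across sessions
      eps_ab <- .gg_epsilon(y[, 2L, ] - y[, 1L, ])
    }
  }
  data.frame(
    F_condition = f_a, df1_condition = df_a, df2_condition = s - 1,
    p_condition = pf(f_a, df_a, s - 1, lower.tail = FALSE),
    F_time = f_b, df1_time = df_b * eps_b, df2_time = df_bs * eps_b,
    p_time = pf(f_b, df_b * eps_b, df_bs * eps_b, lower.tail = FALSE),
    F_interaction = f_ab, df1_interaction = df_ab * eps_ab,
    df2_interaction = df_abs * eps_ab,
    p_interaction = pf(f_ab, df_ab * eps_ab, df_abs * eps_ab,
                       lower.tail = FALSE))
}

# Greenhouse-Geisser epsilon from subject x level score matrix
.gg_epsilon <- function(scores) {
  b <- ncol(scores)
  M <- stats::contr.helmert(b)
  M <- qr.Q(qr(M))                       # orthonormal contrasts
  S <- crossprod(M, stats::cov(scores)) %*% M
  tr <- sum(diag(S))
  eps <- tr^2 / ((b - 1) * sum(S^2))
  min(max(eps, 1 / (b - 1)), 1)
}

#' Benjamini-Hochberg FDR adjustment with rejection set
#'
#' Step-up adjusted q-values (`q_(i) = min_{j >= i} p_(j) m / j`, via
#' `p.adjust(method = "BH")`) and the indices rejected at level `alpha`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list with `q` (same order as `p`) and integer `rejected`.
#' @export
fdrBH <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  list(q = q, rejected = which(q < alpha))
}

#' Post hoc paired contrasts RW vs SR at each time of day
#'
#' Paired t-test of SR against RW at each of the four sessions, reporting
#' the mean difference (SR - RW), t, p, and the direction. Uncorrected by
#' default, matching the convention of reporting per-time contrasts after
#' a significant main effect; `correction = "bonferroni"` multiplies p by
#' the number of sessions.
#'
#' @inheritParams rmAnova
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @return data.frame with one row per session.
#' @export
posthocContrasts <- function(values, subject, condition, session,
                             correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  subject <- as.character(subject)
  sess_lv <- sort(unique(as.character(session)))
  rows <- lapply(sess_lv, function(tt) {
    sel <- session == tt
    sub <- subject[sel]; cond <- condition[sel]; v <- values[sel]
    subj_lv <- sort(unique(sub))
    d <- v[cond == "SR"][match(subj_lv, sub[cond == "SR"])] -
      v[cond == "RW"][match(subj_lv, sub[cond == "RW"])]
    n <- length(d)
    if (n < 2L) {
      tstat <- NA_real_; p <- NA_real_
    } else if (sd(d) == 0) {
      tstat <- 0; p <- 1
    } else {
      tstat <- mean(d) / (sd(d) / sqrt(n))
      p <- 2 * pt(abs(tstat), n - 1, lower.tail = FALSE)
    }
    data.frame(session = tt, mean_diff = mean(d), t = tstat,
               df = n - 1, p = p,
               direction = if (mean(d) > 0) "SR>RW" else
                 if (mean(d) < 0) "SR<RW" else "equal",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (correction == "bonferroni") out$p <- pmin(out$p * nrow(out), 1)
  out
}

#' Run the repeated-measures ANOVA over every cell of a metric panel
#'
#' Applies [rmAnova()] per (measure, density, node) cell of a long-form
#' panel and adjusts the p-values with Benjamini-Hochberg FDR. The
#' default correction family is the set of density-level p-values within
#' one measure x node x factor (25 tests for the canonical sweep);
#' `family = "measures"` widens the family across measures.
#' Degenerate cells (zero error variance) yield `NA` with a warning
#' rather than aborting the sweep.
#'
#' @param panel data.frame with columns `subject`, `condition`,
#'   `session`, `density`, `measure`, `value` and optionally `node`
#'   (absent or `"global"` for global measures).
#' @param alpha FDR level.
#' @param family `"densities"` (default) or `"measures"`.
#' @param ggCorrection passed to [rmAnova()].
#' @return data.frame with one row per cell: the [rmAnova()] columns
#'   plus `measure`, `density`, `node`, and FDR-adjusted `q_condition`,
#'   `q_time`, `q_interaction`.
#' @export
anovaPanel <- function(panel, alpha = 0.05,
                       family = c("densities", "measures"),
                       ggCorrection = FALSE) {
  family <- match.arg(family)
  if (is.null(panel$node)) panel$node <- "global"
  cells <- unique(panel[, c("measure", "density", "node")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- panel$measure == cells$measure[i] &
      panel$density == cells$density[i] & panel$node == cells$node[i]
    cell <- panel[sel, ]
    res <- tryCatch(
      rmAnova(cell$value, cell$subject, cell$condition, cell$session,
              ggCorrection = ggCorrection),
      error = function(e) {
        warning(sprintf("cell %s / %.2f / %s: %s", cells$measure[i],
                        cells$density[i], cells$node[i], conditionMessage(e)))
        data.frame(F_condition = NA_real_, df1_condition = NA, df2_condition = NA,
                   p_condition = NA_real_, F_time = NA_real_, df1_time = NA,
                   df2_time = NA, p_time = NA_real_, F_interaction = NA_real_,
                   df1_interaction = NA, df2_interaction = NA,
                   p_interaction = NA_real_)
      })
    cbind(cells[i, , drop = FALSE], res, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  grp <- if (family == "densities")
    interaction(out$measure, out$node, drop = TRUE)
  else factor(out$node)
  for (f in c("condition", "time", "interaction")) {
    pcol <- paste0("p_", f); qcol <- paste0("q_", f)
    out[[qcol]] <- NA_real_
    for (g in levels(grp)) {
      sel <- grp == g & !is.na(out[[pcol]])
      out[[qcol]][sel] <- p.adjust(out[[pcol]][sel], method = "BH")
    }
  }
  out
}

#' Table-2-style ROI summarisation over a density sweep
#'
#' For each node and measure, counts the densities at which the
#' FDR-adjusted q fell below `alpha` for the condition and time factors,
#' and flags the node when that count exceeds half of the densities
#' tested (strictly more than half: >= 13 of 25 for the canonical
#' sweep).
#'
#' @param anovaResults output of [anovaPanel()] (nodal measures).
#' @param alpha significance level applied to the q-values.
#' @return data.frame with one row per node x measure:
#'   `n_densities_tested`, `n_significant_condition`,
#'   `n_significant_time`, `flagged_condition`, `flagged_time`.
#' @export
summarizeRoi <- function(anovaResults, alpha = 0.05) {
  cells <- unique(anovaResults[, c("node", "measure")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- anovaResults$node == cells$node[i] &
      anovaResults$measure == cells$measure[i]
    sub <- anovaResults[sel, ]
    n_d <- nrow(sub)
    n_c <- sum(sub$q_condition < alpha, na.rm = TRUE)
    n_t <- sum(sub$q_time < alpha, na.rm = TRUE)
    data.frame(node = cells$node[i], measure = cells$measure[i],
               n_densities_tested = n_d,
               n_significant_condition = n_c, n_significant_time = n_t,
               flagged_condition = n_c > floor(n_d / 2),
               flagged_time = n_t > floor(n_d / 2),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
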