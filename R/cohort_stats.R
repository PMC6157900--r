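#' Propensity score matching on age and gender
#'
#' Logistic propensity model for group membership, followed by caliper-based
#' nearest-neighbour matching without replacement (caliper in SD of the
#' logit). Returns the matched subgroups and covariate balance diagnostics
#' (Wilcoxon rank-sum for continuous covariates, Yates-corrected chi-square
#' for gender) before and after matching.
#'
#' @param subjects data frame with a `group` column (two levels; the first
#'   level after factoring is modelled as the "treated" group) and the
#'   matching covariates.
#' @param covariates covariate column names used in the propensity model.
#' @param caliper caliper width in SD of the logit propensity score.
#' @param seed seed controlling the (randomised) matching order.
#' @return object of class `match_result`: `matched` (data frame of matched
#'   pairs), `kept_ids`, `balance` (per-covariate p-values before/after and
#'   standardized mean differences), `scores`.
#' @export
propensity_score_match <- function(subjects, covariates = c("age", "gender"),
                                   caliper = 0.2, seed = 1) {
  stopifnot(all(covariates %in% names(subjects)))
  g <- factor(subjects$group)
  if (nlevels(g) != 2) stop("need exactly two groups")
  if (any(table(g) == 0)) stop("both groups must be non-empty")
  treated <- g == levels(g)[1]

  df <- subjects[, covariates, drop = FALSE]
  df$..t <- as.numeric(treated)
  fml <- as.formula(paste("..t ~", paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(glm(fml, data = df, family = binomial()))
  if (!fit$converged || any(abs(coef(fit)) > 50, na.rm = TRUE))
    stop("propensity model did not converge (possible complete ",
         "separation); consider exact matching or a wider caliper")
  lp <- predict(fit, type = "link")
  cal <- caliper * sd(lp)

  it <- which(treated); ic <- which(!treated)
  set.seed(derive_seed(seed, 31L))
  it <- sample(it)
  used <- logical(length(lp))
  pairs <- list()
  for (i in it) {
    d <- abs(lp[ic] - lp[i])
    d[used[ic]] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= cal) {
      pairs[[length(pairs) + 1L]] <- c(i, ic[j])
      used[ic[j]] <- TRUE
    }
  }
  kept <- if (length(pairs)) sort(unlist(pairs)) else integer(0)
  matched <- if (length(pairs))
    data.frame(treated = vapply(pairs, `[`, 1L, 1),
               control = vapply(pairs, `[`, 1L, 2))
  else data.frame(treated = integer(0), control = integer(0))

  bal <- function(idx) {
    lapply(covariates, function(cv) {
      x <- subjects[[cv]][idx]; tt <- treated[idx]
      if (is.numeric(x)) {
        p <- if (length(unique(tt)) == 2)
          suppressWarnings(wilcox.test(x[tt], x[!tt], exact = FALSE)$p.value)
        else NA_real_
        smd <- (mean(x[tt]) - mean(x[!tt])) /
          sqrt((var(x[tt]) + var(x[!tt])) / 2)
        list(covariate = cv, test = "wilcoxon", p = p, smd = smd)
      } else {
        tb <- table(factor(x), factor(tt))
        p <- if (all(dim(tb) >= 2))
          suppressWarnings(chisq.test(tb, correct = TRUE)$p.value)
        else NA_real_
        list(covariate = cv, test = "chisq_yates", p = p, smd = NA_real_)
      }
    })
  }
  balance <- do.call(rbind, lapply(seq_along(covariates), function(k) {
    before <- bal(seq_along(lp))[[k]]
    after <- if (length(kept) >= 4) bal(kept)[[k]] else
      list(p = NA_real_, smd = NA_real_)
    data.frame(covariate = before$covariate, test = before$test,
               p_before = before$p, p_after = after$p,
               smd_before = before$smd, smd_after = after$smd)
  }))

  structure(list(matched = matched, kept_ids = kept, balance = balance,
                 scores = lp, caliper_logit = cal,
                 n_before = as.vector(table(g)),
                 n_after = c(nrow(matched), nrow(matched))),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("<match_result> ", nrow(x$matched), " matched pairs (group sizes ",
      paste(x$n_before, collapse = "/"), " before)\n", sep = "")
  print(x$balance, row.names = FALSE)
  invisible(x)
}

## within-subject mid-ranks of the observed conditions; NA rows untouched
row_midranks <- function(tab) {
  t(apply(tab, 1, function(r) {
    out <- rep(NA_real_, length(r))
    obs <- !is.na(r)
    out[obs] <- rank(r[obs])
    out
  }))
}

## rank quadratic form shared by the global test and the pairwise contrasts:
## A_k = sum_i w_i (r_ik - (n_i+1)/2), w_i = sqrt(12/(n_i+1)),
## Sigma = sum_i w_i^2 Cov_i with Cov from within-subject rank
## exchangeability under H0.
wittkowski_core <- function(tab) {
  tab <- as.matrix(tab)
  K <- ncol(tab)
  if (K < 2) stop("need at least 2 conditions")
  obs <- !is.na(tab)
  ni <- rowSums(obs)
  keep <- ni >= 2
  if (!any(keep)) stop("no subject has 2 or more observed conditions")
  tab <- tab[keep, , drop = FALSE]; obs <- obs[keep, , drop = FALSE]
  ni <- ni[keep]
  R <- row_midranks(tab)
  w <- sqrt(12 / (ni + 1))
  Ac <- sweep(R, 1, (ni + 1) / 2, "-") * w
  A <- colSums(Ac, na.rm = TRUE)
  Sigma <- matrix(0, K, K)
  for (i in seq_along(ni)) {
    o <- which(obs[i, ])
    Sigma[o, o] <- Sigma[o, o] - 1
    diag(Sigma)[o] <- diag(Sigma)[o] + ni[i] # (-1) + n_i on the diagonal
  }
  list(A = A, Sigma = Sigma, K = K, n_subjects = length(ni))
}

## Moore-Penrose pseudo-inverse via eigen decomposition (Sigma is symmetric)
pinv_sym <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  pos <- e$values > tol * max(e$values, 0)
  if (!any(pos)) return(list(inv = S * 0, rank = 0))
  inv <- e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
  list(inv = inv, rank = sum(pos))
}

#' Friedman-type rank test for unbalanced repeated measures
#'
#' Global test for a condition effect in a subjects x conditions table with
#' missing entries, built from within-subject mid-rankings of the observed
#' conditions aggregated into a chi-square quadratic form (the construction
#' used for consistent multiple comparisons in unbalanced designs with
#' missing data). On a complete balanced table without ties the statistic
#' reduces exactly to Friedman's chi-square.
#'
#' @param tab numeric matrix, subjects in rows, conditions in columns, `NA`
#'   for missing.
#' @return list with `statistic`, `df`, `p.value`, `n_subjects`.
#' @export
wittkowski_test <- function(tab) {
  core <- wittkowski_core(tab)
  if (sum(abs(core$A)) < 1e-12)
    return(list(statistic = 0, df = core$K - 1, p.value = 1,
                n_subjects = core$n_subjects))
  pi_ <- pinv_sym(core$Sigma)
  stat <- drop(core$A %*% pi_$inv %*% core$A)
  df <- min(core$K - 1, pi_$rank)
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE),
       n_subjects = core$n_subjects)
}

#' Scheffe-adjusted pairwise condition contrasts
#'
#' All pairwise contrasts of the rank statistic underlying
#' [wittkowski_test()], with a Scheffe-type family-wise adjustment: the
#' squared standardized contrast is referred to the chi-square distribution
#' with K-1 degrees of freedom (instead of 1), so adjusted p-values are
#' never smaller than unadjusted ones and any contrast can be tested
#' post hoc.
#'
#' @param tab as in [wittkowski_test()].
#' @return data frame with `cond_a`, `cond_b`, `statistic`, `p_unadjusted`,
#'   `p_adjusted`.
#' @export
scheffe_pairwise <- function(tab) {
  core <- wittkowski_core(tab)
  K <- core$K
  cn <- colnames(tab) %||% paste0("C", seq_len(K))
  out <- list()
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    ctr <- numeric(K); ctr[a] <- 1; ctr[b] <- -1
    num <- drop(ctr %*% core$A)
    v <- drop(ctr %*% core$Sigma %*% ctr)
    z2 <- if (v > 0) num^2 / v else 0
    out[[length(out) + 1L]] <- data.frame(
      cond_a = cn[a], cond_b = cn[b], statistic = z2,
      p_unadjusted = pchisq(z2, 1, lower.tail = FALSE),
      p_adjusted = pchisq(z2, K - 1, lower.tail = FALSE))
  }
  do.call(rbind, out)
}

#' Spearman correlation matrix with significance mask and clustering
#'
#' Pairwise-complete Spearman correlations between variables, a mask of
#' non-significant pairs (p >= `alpha`, no multiplicity adjustment by
#' default, mirroring the usual white-square display; Benjamini-Hochberg
#' optional), and average-linkage hierarchical clustering on the distance
#' `1 - |R|`. Constant variables are excluded from clustering and reported.
#'
#' @param tab data frame or matrix of variables in columns.
#' @param alpha significance level for the mask.
#' @param adjust `"none"` or `"BH"`.
#' @return object of class `correlation_cluster`: `R`, `p`,
#'   `nonsig_mask`, `order`, `hclust`, `excluded`.
#' @export
correlation_cluster <- function(tab, alpha = 0.05,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  tab <- as.data.frame(tab)
  stopifnot(ncol(tab) >= 3)
  cc <- vapply(tab, function(x) sd(x, na.rm = TRUE), 1)
  excluded <- names(tab)[!is.finite(cc) | cc == 0]
  use <- setdiff(names(tab), excluded)
  if (length(use) < 3) stop("fewer than 3 non-constant variables")
  m <- as.matrix(tab[, use])
  npair <- crossprod(!is.na(m))
  if (any(npair[upper.tri(npair)] < 5))
    stop("fewer than 5 pairwise-complete observations for some pair")
  R <- cor(m, method = "spearman", use = "pairwise.complete.obs")
  K <- ncol(R)
  P <- matrix(NA_real_, K, K, dimnames = dimnames(R))
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    ## t-approximation for the Spearman coefficient (mid-ranks, ties OK)
    n <- npair[a, b]; r <- R[a, b]
    tstat <- r * sqrt((n - 2) / max(1e-12, 1 - r^2))
    P[a, b] <- P[b, a] <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  diag(P) <- 0
  pv <- P[upper.tri(P)]
  if (adjust == "BH") {
    pv <- stats::p.adjust(pv, "BH")
    P[upper.tri(P)] <- pv
    P[lower.tri(P)] <- t(P)[lower.tri(P)]
  }
  hc <- hclust(as.dist(1 - abs(R)), method = "average")
  structure(list(R = R, p = P, nonsig_mask = P >= alpha,
                 order = hc$order, hclust = hc, excluded = excluded,
                 alpha = alpha, adjust = adjust),
            class = "correlation_cluster")
}

#' Two-group comparisons
#'
#' Continuous variables: Wilcoxon rank-sum with the normal approximation
#' (mid-ranks for ties). Categorical variables: Pearson chi-square with
#' Yates continuity correction on the 2 x K contingency table.
#'
#' @param x,y the two groups' values (vectors; factors/characters are
#'   treated as categorical).
#' @param kind `"continuous"`, `"categorical"`, or `"auto"`.
#' @return list with `statistic`, `p.value`, `method`.
#' @export
two_group_tests <- function(x, y, kind = c("auto", "continuous",
                                           "categorical")) {
  kind <- match.arg(kind)
  if (length(x) == 0 || length(y) == 0) stop("empty group")
  if (kind == "auto")
    kind <- if (is.numeric(x) && is.numeric(y)) "continuous" else "categorical"
  if (kind == "continuous") {
    ht <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    list(statistic = unname(ht$statistic), p.value = ht$p.value,
         method = "wilcoxon_normal_approx")
  } else {
    lev <- union(unique(as.character(x)), unique(as.character(y)))
    tb <- rbind(table(factor(as.character(x), levels = lev)),
                table(factor(as.character(y), levels = lev)))
    ht <- suppressWarnings(chisq.test(tb, correct = TRUE))
    list(statistic = unname(ht$statistic), p.value = ht$p.value,
         method = "chisq_yates")
  }
}
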