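# Placement comparison: mixed-model ANOVA of daily distances.
#
# Model (one algorithm at a time):
#   distance ~ placement (fixed)
#            + (1 | tracker) + (1 | tracker:placement) + (1 | date)
# fitted by REML with variance components constrained non-negative (lme4).
# In a deployment where the animal collars reuse trackers from the static
# phase, tracker and tracker:placement are distinct grouping factors; when
# every tracker has a single placement the two are aliased and the duplicate
# term is dropped (noted in the summary).
#
# Inference: Wald t/F statistics on the fixed effects with
# Satterthwaite-type denominator degrees of freedom computed from the REML
# information matrix (per-contrast delta method; Fai-Cornelius combination
# for multi-degree-of-freedom tests).  If that computation degenerates, the
# containment convention (tracker-placement units minus placements) is used
# instead.  Exact p-value parity with any particular mixed-model
# implementation is not claimed.  Pairwise p-values are unadjusted by
# default (letters reflect unadjusted tests), with a Tukey option.

#' Compare daily distances across tracker placements
#'
#' Fits the mixed model above for a single algorithm's daily distances and
#' returns least-squares means with standard errors, per-placement tests
#' against zero, all pairwise placement comparisons with a compact letter
#' display, the overall placement F-test, and the static (Indoor, Outdoor)
#' vs. non-static (Animal) contrast.
#'
#' @param daily daily-distance rows for one algorithm (see [compute_all()]).
#' @param alpha significance level for the letter display, default 0.05.
#' @param adjust `"none"` (default) or `"tukey"` for pairwise p-values.
#' @return an object of class `placement_summary`: a list with `algorithm`,
#'   `table` (placement, ls_mean, se, p_vs_zero, letter), `pairwise`
#'   (symmetric p-value matrix), `p_placement`, `f_placement`, `ddf`,
#'   `static_contrast` (estimate, se, p for non-static minus static means),
#'   `alpha`, `method` (`"lmm"` or `"lm_fallback"`), and `notes`.
#' @export
fit_placement_model <- function(daily, alpha = 0.05,
                                adjust = c("none", "tukey")) {
  adjust <- match.arg(adjust)
  alg <- unique(daily$algorithm)
  if (length(alg) != 1)
    stop("fit_placement_model() expects rows for a single algorithm; got: ",
         paste(alg, collapse = ", "))
  notes <- character(0)
  d <- daily[!is.na(daily$distance_m), , drop = FALSE]
  if (nrow(d) < nrow(daily))
    notes <- c(notes, sprintf("%d tracker-day(s) with missing distance dropped",
                              nrow(daily) - nrow(d)))
  d$placement <- factor(d$placement,
                        levels = intersect(.placements, unique(d$placement)))
  if (nlevels(d$placement) < 2)
    stop("need at least two placements to compare")
  per <- table(unique(d[c("tracker_id", "placement")])$placement)
  if (any(per < 1) || nrow(d) < nlevels(d$placement) + 2)
    stop("too few tracker-days per placement to fit the model")
  d$tracker_f <- factor(d$tracker_id)
  d$unit_f <- factor(paste(d$tracker_id, d$placement, sep = ":"))
  d$date_f <- factor(as.character(d$date))

  aliased <- nlevels(d$unit_f) == nlevels(d$tracker_f)
  form <- if (aliased) {
    notes <- c(notes, "tracker and tracker:placement aliased; one random term used")
    distance_m ~ 0 + placement + (1 | unit_f) + (1 | date_f)
  } else {
    distance_m ~ 0 + placement + (1 | tracker_f) + (1 | unit_f) + (1 | date_f)
  }

  method <- "lmm"
  fitted <- tryCatch({
    fit <- suppressMessages(lme4::lmer(form, data = d, REML = TRUE,
                                       control = lme4::lmerControl(
                                         check.conv.singular = "ignore")))
    list(beta = lme4::fixef(fit), V = as.matrix(stats::vcov(fit)),
         satt = .satterthwaite_machinery(fit),
         singular = lme4::isSingular(fit))
  }, error = function(e) e)
  if (inherits(fitted, "error")) {
    warning("mixed-model fit failed (", conditionMessage(fitted),
            "); falling back to fixed-effects ANOVA")
    notes <- c(notes, paste("FALLBACK: fixed-effects ANOVA;",
                            conditionMessage(fitted)))
    method <- "lm_fallback"
    fit <- stats::lm(distance_m ~ 0 + placement, data = d)
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    rdf <- stats::df.residual(fit)
    df_contrast <- function(L) rdf
    df_ftest <- function(C) rdf
  } else {
    if (fitted$singular)
      notes <- c(notes,
                 "singular fit: one or more variance components estimated 0")
    beta <- fitted$beta
    V <- fitted$V
    # containment convention as the fallback df when the Satterthwaite
    # computation degenerates at a variance boundary
    contain <- max(1L, nlevels(d$unit_f) - nlevels(d$placement))
    df_contrast <- function(L) {
      v <- if (is.null(fitted$satt)) NA_real_ else fitted$satt$df_contrast(L)
      if (is.finite(v) && v > 0) v else contain
    }
    df_ftest <- function(C) {
      v <- if (is.null(fitted$satt)) NA_real_ else fitted$satt$df_ftest(C)
      if (is.finite(v) && v > 0) v else contain
    }
  }

  lev <- levels(d$placement)
  k <- length(lev)
  names(beta) <- sub("^placement", "", names(beta))
  beta <- beta[lev]
  se <- sqrt(diag(V))[paste0("placement", lev)]
  t_zero <- beta / se
  df_zero <- vapply(seq_len(k), function(i) {
    L <- numeric(k); L[i] <- 1; df_contrast(L)
  }, numeric(1))
  p_zero <- ifelse(is.finite(t_zero),
                   2 * stats::pt(-abs(t_zero), df_zero), NA_real_)
  if (anyNA(p_zero))
    notes <- c(notes, "zero-variance group(s): mu=0 test undefined (NA)")

  # pairwise comparisons
  pairwise <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    L <- numeric(k); L[i] <- 1; L[j] <- -1
    est <- sum(L * beta)
    s <- sqrt(drop(t(L) %*% V %*% L))
    tv <- est / s
    dfp <- df_contrast(L)
    p <- if (!is.finite(tv)) {
      if (est == 0) 1 else NA_real_
    } else if (adjust == "tukey") {
      stats::ptukey(sqrt(2) * abs(tv), nmeans = k, df = dfp,
                    lower.tail = FALSE)
    } else {
      2 * stats::pt(-abs(tv), dfp)
    }
    pairwise[i, j] <- pairwise[j, i] <- p
  }
  diag(pairwise) <- 1

  # overall placement F-test (Wald)
  C <- matrix(0, k - 1, k)
  for (i in seq_len(k - 1)) { C[i, i] <- 1; C[i, k] <- -1 }
  cb <- C %*% beta
  f_stat <- tryCatch(
    drop(t(cb) %*% solve(C %*% V %*% t(C)) %*% cb) / (k - 1),
    error = function(e) NA_real_)
  ddf <- df_ftest(C)
  p_placement <- if (is.finite(f_stat)) {
    stats::pf(f_stat, k - 1, ddf, lower.tail = FALSE)
  } else if (all(cb == 0)) 1 else NA_real_

  # static (Indoor, Outdoor) vs non-static (Animal) means
  static_contrast <- NULL
  stat_lev <- intersect(c("Indoor", "Outdoor"), lev)
  if ("Animal" %in% lev && length(stat_lev) > 0) {
    L <- numeric(k); names(L) <- lev
    L["Animal"] <- 1
    L[stat_lev] <- -1 / length(stat_lev)
    est <- sum(L * beta)
    s <- sqrt(drop(t(L) %*% V %*% L))
    pc <- if (s > 0) 2 * stats::pt(-abs(est / s), df_contrast(L)) else
      if (est == 0) 1 else NA_real_
    static_contrast <- list(estimate = est, se = s, p = pc)
  }

  letters <- letter_grouping(pairwise, alpha = alpha, means = beta)
  res <- list(algorithm = alg,
              table = data.frame(placement = lev, ls_mean = unname(beta),
                                 se = unname(se), p_vs_zero = unname(p_zero),
                                 letter = letters[lev],
                                 stringsAsFactors = FALSE),
              pairwise = pairwise,
              p_placement = p_placement, f_placement = f_stat, ddf = ddf,
              static_contrast = static_contrast,
              alpha = alpha, adjust = adjust, method = method, notes = notes)
  class(res) <- "placement_summary"
  res
}

# Satterthwaite denominator degrees of freedom for a fitted random-intercept
# mixed model, computed directly from the marginal covariance
#   Sigma(psi) = sigma^2 I + sum_k tau_k^2 Z_k Z_k',   psi = (tau^2, sigma^2).
# For a contrast L on the fixed effects, g(psi) = L' (X' Sigma^-1 X)^-1 L and
#   df = 2 g^2 / (grad_g' A grad_g),
# with A the inverse REML information I_ij = tr(P G_i P G_j) / 2,
# P = Sigma^-1 - Sigma^-1 X (X'Sigma^-1 X)^-1 X'Sigma^-1, G_i = dSigma/dpsi_i.
# Multi-df tests use the Fai-Cornelius combination over the eigen-contrasts
# of C V C'.  Everything is dense; model sizes here are a few hundred rows.
.satterthwaite_machinery <- function(fit) {
  tryCatch({
    X <- as.matrix(lme4::getME(fit, "X"))
    n <- nrow(X)
    flist <- lme4::getME(fit, "flist")
    asgn <- attr(flist, "assign")  # term -> grouping factor
    vc <- lme4::VarCorr(fit)
    # scalar random intercepts only (all models fitted here are)
    Zs <- lapply(flist, function(f) {
      Z <- stats::model.matrix(~ 0 + f)
      Z %*% t(Z)
    })
    tau2 <- vapply(seq_along(Zs), function(i) {
      as.numeric(vc[[which(asgn == i)[1]]][1, 1])
    }, numeric(1))
    sig2 <- stats::sigma(fit)^2
    psi <- c(tau2, sig2)
    G <- c(Zs, list(diag(n)))
    Sigma <- matrix(0, n, n)
    for (i in seq_along(psi)) Sigma <- Sigma + psi[i] * G[[i]]
    Si <- solve(Sigma)
    SiX <- Si %*% X
    W <- crossprod(X, SiX)
    V <- solve(W)
    P <- Si - SiX %*% tcrossprod(V, SiX)
    # components estimated exactly at the zero boundary contribute nothing
    # to the sampling variance of g (zero Jacobian on the sd scale, the
    # standard convention); drop them from the delta method
    keep <- c(sqrt(tau2 / sig2) > 1e-4, TRUE)  # lme4's singularity tol
    Gk <- G[keep]
    PG <- lapply(Gk, function(g) P %*% g)
    np <- length(PG)
    info <- matrix(0, np, np)
    for (i in seq_len(np)) for (j in i:np) {
      info[i, j] <- info[j, i] <- 0.5 * sum(PG[[i]] * t(PG[[j]]))
    }
    A <- solve(info)
    dV <- lapply(Gk, function(g) {
      M <- crossprod(SiX, g %*% SiX)   # X' Si G Si X
      V %*% M %*% V
    })
    df_contrast <- function(L) {
      g <- drop(t(L) %*% V %*% L)
      if (g <= 0) return(NA_real_)
      grad <- vapply(dV, function(dv) drop(t(L) %*% dv %*% L), numeric(1))
      varg <- drop(t(grad) %*% A %*% grad)
      if (!is.finite(varg) || varg <= 0) return(Inf)
      2 * g^2 / varg
    }
    df_ftest <- function(C) {
      q <- nrow(C)
      M <- C %*% V %*% t(C)
      e <- eigen(M, symmetric = TRUE)
      nu <- vapply(seq_len(q), function(m) {
        df_contrast(drop(t(e$vectors[, m]) %*% C))
      }, numeric(1))
      ok <- is.finite(nu) & nu > 2
      if (!any(ok) && !any(is.infinite(nu))) return(NA_real_)
      # each eigen-contrast contributes nu/(nu-2); infinite df contributes 1
      E <- sum(nu[ok] / (nu[ok] - 2)) + sum(is.infinite(nu))
      if (E <= q) return(Inf)
      2 * E / (E - q)
    }
    list(df_contrast = df_contrast, df_ftest = df_ftest, vcov_vc = A,
         psi = psi)
  }, error = function(e) NULL)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Placements whose pairwise comparison is not significant at `alpha` share
#' a letter (insert-and-absorb construction).  Letters are assigned in order
#' of decreasing mean when `means` is supplied, so `"a"` marks the largest
#' group, as in conventional ANOVA tables.
#'
#' @param pairwise_p symmetric matrix of pairwise p-values with dimnames.
#' @param alpha significance level.
#' @param means optional named vector used to order letter assignment.
#' @return named character vector of letter labels.
#' @export
letter_grouping <- function(pairwise_p, alpha = 0.05, means = NULL) {
  stopifnot(is.matrix(pairwise_p), nrow(pairwise_p) == ncol(pairwise_p))
  groups <- rownames(pairwise_p)
  k <- length(groups)
  ord <- if (is.null(means)) seq_len(k) else order(means[groups],
                                                   decreasing = TRUE)
  # start with one letter covering everything; split on each significant pair
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    if (is.na(pairwise_p[i, j]) || pairwise_p[i, j] >= alpha) next
    new_sets <- list()
    for (s in sets) {
      if (all(c(i, j) %in% s)) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) for (b in seq_along(new_sets)) {
      if (a != b && keep[a] && keep[b] &&
          all(new_sets[[a]] %in% new_sets[[b]]) &&
          length(new_sets[[a]]) < length(new_sets[[b]])) keep[a] <- FALSE
    }
    new_sets <- new_sets[keep]
    keep2 <- !duplicated(lapply(new_sets, sort))
    sets <- new_sets[keep2]
  }
  # order letters by the highest-ranked member of each set
  rank_of <- match(seq_len(k), ord)
  set_rank <- vapply(sets, function(s) min(rank_of[s]), numeric(1))
  sets <- sets[order(set_rank)]
  out <- setNames(rep("", k), groups)
  for (si in seq_along(sets)) {
    for (g in sets[[si]]) out[g] <- paste0(out[g], letters[si])
  }
  out
}

#' @export
print.placement_summary <- function(x, ...) {
  cat("Placement comparison -", x$algorithm,
      if (x$method == "lm_fallback") "(fixed-effects fallback)" else "(mixed model)",
      "\n")
  tab <- x$table
  tab$ls_mean <- round(tab$ls_mean, 1)
  tab$se <- round(tab$se, 1)
  tab$p_vs_zero <- signif(tab$p_vs_zero, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("placement effect: F = %.2f on %d, %.1f df; p = %.4g\n",
              x$f_placement, nrow(tab) - 1, x$ddf, x$p_placement))
  if (!is.null(x$static_contrast))
    cat(sprintf("non-static vs static: %.1f m (SE %.1f), p = %.4g\n",
                x$static_contrast$estimate, x$static_contrast$se,
                x$static_contrast$p))
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}
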