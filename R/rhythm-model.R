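# Multinomial rhythm-probability models: penalized maximum likelihood with
# thin-plate spline smooths and ridge-penalized group effects, K-fold
# cross-validated predictive density, and stacking of predictive
# distributions.

#' Specify a candidate rhythm-probability model
#'
#' Terms are named after covariate columns: `"x"` enters linearly (or as
#' treatment-coded dummies when categorical), `"s(x)"` as a thin-plate
#' regression smooth that shrinks to a straight line under heavy
#' penalization, and `"s(x):g"` as a separate smooth of `x` within each
#' level of the categorical `g` (add `"g"` itself for the main effect).
#' Grouping factors receive ridge-penalized indicator coefficients, the
#' penalized-likelihood analogue of group-level (random) intercepts.
#'
#' @param name Model label.
#' @param terms Character vector of term specifications (empty = null
#'   model, intercept and group effects only).
#' @param groups Grouping-factor column names (default bear and season).
#'
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, terms = character(),
                       groups = c("bear_id", "season")) {
  structure(list(name = name, terms = terms, groups = groups),
            class = "model_spec")
}

#' A priori candidate model sets
#'
#' The candidate model lists for the hibernation and active-state
#' analyses: single intrinsic or environmental predictors, selected
#' den-related combinations for hibernation, and day-length models
#' (including the day-length-by-direction interaction) for the active
#' state.
#'
#' @param state `"hibernation"` or `"active"`.
#' @param groups Grouping factors passed to every spec.
#'
#' @return Named list of [model_spec()] objects (15 for hibernation,
#'   13 for the active state), named `m0`, `m1`, ...
#' @export
candidate_models <- function(state = c("hibernation", "active"),
                             groups = c("bear_id", "season")) {
  state <- match.arg(state)
  hib <- list(
    character(),
    "s(body_mass)", "age_class", "sex", "status",
    "s(snow_depth)", "s(day_length)", "s(ta_mean)", "s(open_area)",
    "den_type",
    c("s(open_area)", "s(snow_depth)"),
    c("den_type", "s(snow_depth)"),
    c("s(open_area)", "s(snow_depth)", "status"),
    c("den_type", "s(snow_depth)", "status"),
    c("den_type", "s(snow_depth)", "s(open_area)"))
  act <- list(
    character(),
    "s(body_mass)", "age_class", "sex", "status",
    "day_length_direction", "s(day_length)", "s(ta_mean)", "snow_depth",
    c("s(day_length)", "status"),
    c("s(ta_mean)", "status"),
    c("day_length_direction", "s(day_length):day_length_direction"),
    c("day_length_direction", "s(day_length):day_length_direction",
      "status"))
  terms <- if (state == "hibernation") hib else act
  specs <- lapply(seq_along(terms), function(i)
    model_spec(sprintf("m%d", i - 1L), terms[[i]], groups))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' Thin-plate regression spline basis with penalty
#'
#' Low-rank thin-plate regression spline basis (sum-to-zero constrained)
#' with its quadratic penalty matrix.  The penalty null space is the
#' linear function, so as the smoothing parameter grows the fitted term
#' collapses to a straight line.
#'
#' @param x Numeric covariate (>= `n_basis` distinct values).
#' @param n_basis Basis dimension before constraint absorption.
#'
#' @return List with `X` (basis matrix), `S` (penalty matrix, symmetric
#'   positive semidefinite) and `smooth` (the underlying smooth
#'   construction object, reusable for prediction).
#' @export
spline_basis <- function(x, n_basis = 8) {
  if (length(unique(x)) < 2) stop_br("constant x: cannot build a smooth")
  k <- min(n_basis, length(unique(x)))
  if (k < 3) stop_br("need at least 3 distinct x values for a smooth")
  df <- data.frame(x = x)
  sm <- mgcv::smoothCon(eval(str2lang(sprintf('mgcv::s(x, bs = "tp", k = %d)',
                                              k))),
                        data = df, absorb.cons = TRUE)[[1]]
  list(X = sm$X, S = sm$S[[1]], smooth = sm)
}

# ---- design construction ---------------------------------------------------

# Parse a term string into list(type, var, by).
parse_term <- function(term) {
  m <- regmatches(term, regexec("^s\\(([^)]+)\\)(?::(.+))?$", term,
                                perl = TRUE))[[1]]
  if (length(m) && nzchar(m[2])) {
    list(type = "smooth", var = m[2], by = if (nzchar(m[3])) m[3] else NULL)
  } else {
    list(type = "plain", var = term, by = NULL)
  }
}

spec_columns <- function(spec) {
  vars <- vapply(spec$terms, function(tm) parse_term(tm)$var, "")
  bys <- unlist(lapply(spec$terms, function(tm) parse_term(tm)$by))
  unique(c(vars, bys, spec$groups))
}

# Build the model matrix and penalty structure for a spec on `data`.
# Returns X plus per-block penalties and everything needed to rebuild the
# design on new data.
build_design <- function(spec, data, basis_k = 8) {
  n <- nrow(data)
  blocks <- list(list(name = "(Intercept)", X = matrix(1, n, 1),
                      kind = "fixed"))
  info <- list()
  for (tm in spec$terms) {
    pt <- parse_term(tm)
    v <- pt$var
    if (!v %in% names(data)) stop_br("unknown covariate in spec: ", v)
    if (pt$type == "smooth") {
      sdat <- data[, unique(c(v, pt$by)), drop = FALSE]
      if (!is.null(pt$by)) sdat[[pt$by]] <- factor(sdat[[pt$by]])
      k <- min(basis_k, length(unique(sdat[[v]])))
      if (k < 3) stop_br("too few distinct values of ", v, " for a smooth")
      scall <- if (is.null(pt$by)) {
        sprintf('mgcv::s(%s, bs = "tp", k = %d)', v, k)
      } else {
        sprintf('mgcv::s(%s, by = %s, bs = "tp", k = %d)', v, pt$by, k)
      }
      sms <- mgcv::smoothCon(eval(str2lang(scall)), data = sdat,
                             absorb.cons = TRUE)
      for (sm in sms) {
        blocks[[length(blocks) + 1]] <- list(
          name = sm$label, X = sm$X, kind = "smooth", S = sm$S[[1]],
          smooth = sm)
      }
      info[[tm]] <- list(type = "smooth", smooths = sms, by = pt$by)
    } else if (is.numeric(data[[v]])) {
      blocks[[length(blocks) + 1]] <- list(
        name = v, X = matrix(data[[v]], ncol = 1, dimnames = list(NULL, v)),
        kind = "fixed")
      info[[tm]] <- list(type = "linear", var = v)
    } else {
      f <- factor(data[[v]])
      Xf <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(Xf) <- paste0(v, levels(f)[-1])
      blocks[[length(blocks) + 1]] <- list(name = v, X = Xf, kind = "fixed")
      info[[tm]] <- list(type = "factor", var = v, levels = levels(f))
    }
  }
  for (g in spec$groups) {
    if (!g %in% names(data)) next
    f <- factor(data[[g]])
    if (nlevels(f) < 2) next
    Xg <- stats::model.matrix(~ f - 1)
    colnames(Xg) <- paste0(g, levels(f))
    blocks[[length(blocks) + 1]] <- list(name = g, X = Xg, kind = "ridge",
                                         levels = levels(f), group = g)
    info[[paste0("group:", g)]] <- list(type = "group", var = g,
                                        levels = levels(f))
  }
  X <- do.call(cbind, lapply(blocks, `[[`, "X"))
  colnames(X) <- unlist(lapply(blocks, function(b) {
    cn <- colnames(b$X)
    if (is.null(cn)) cn <- if (ncol(b$X) == 1) b$name else
      paste0(b$name, ".", seq_len(ncol(b$X)))
    cn
  }))
  offsets <- cumsum(c(0, vapply(blocks, function(b) ncol(b$X), 0L)))
  penalties <- list()
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    idx <- (offsets[i] + 1):(offsets[i] + ncol(b$X))
    if (b$kind == "smooth") {
      penalties[[length(penalties) + 1]] <- list(idx = idx, S = b$S,
                                                 kind = "smooth")
    } else if (b$kind == "ridge") {
      penalties[[length(penalties) + 1]] <- list(idx = idx,
                                                 S = diag(length(idx)),
                                                 kind = "ridge")
    }
  }
  list(X = X, penalties = penalties, info = info, blocks = blocks)
}

# Rebuild the design on new data from a stored design description.
predict_design <- function(design, newdata) {
  n <- nrow(newdata)
  cols <- list()
  for (b in design$blocks) {
    if (b$kind == "smooth") {
      sm <- b$smooth
      need <- c(sm$term, if (!is.null(sm$by) && sm$by != "NA") sm$by)
      nd <- newdata[, intersect(need, names(newdata)), drop = FALSE]
      if (!is.null(sm$by) && sm$by != "NA" && sm$by %in% names(nd)) {
        nd[[sm$by]] <- factor(nd[[sm$by]])
      }
      cols[[length(cols) + 1]] <- mgcv::PredictMat(sm, nd)
    } else if (b$kind == "ridge") {
      f <- as.character(newdata[[b$group]])
      Xg <- matrix(0, n, length(b$levels))
      hit <- match(f, b$levels)
      ok <- !is.na(hit)
      Xg[cbind(which(ok), hit[ok])] <- 1   # unseen groups get zero effect
      cols[[length(cols) + 1]] <- Xg
    } else if (b$name == "(Intercept)") {
      cols[[length(cols) + 1]] <- matrix(1, n, 1)
    } else if (ncol(b$X) == 1 && identical(colnames(b$X), b$name)) {
      cols[[length(cols) + 1]] <- matrix(newdata[[b$name]], ncol = 1)
    } else {
      # treatment-coded factor
      all_lv <- factor_levels(design, b$name)
      lv <- all_lv[-1]
      f <- as.character(newdata[[b$name]])
      if (any(!f %in% all_lv)) {
        stop_br("unseen level(s) for ", b$name, ": ",
                paste(unique(f[!f %in% all_lv]), collapse = ", "))
      }
      Xf <- matrix(0, n, length(lv))
      hit <- match(f, lv)
      ok <- !is.na(hit)
      Xf[cbind(which(ok), hit[ok])] <- 1
      cols[[length(cols) + 1]] <- Xf
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- colnames(design$X)
  X
}

# Stored level set of a treatment-coded factor term.
factor_levels <- function(design, var) {
  for (inf in design$info) {
    if (identical(inf$type, "factor") && identical(inf$var, var)) {
      return(inf$levels)
    }
  }
  stop_br("no stored levels for factor ", var)
}

# ---- penalized multinomial fit ---------------------------------------------

# Combined penalty matrix (p x p) for given smoothing parameters,
# scaled per observation count by the caller.
penalty_matrix <- function(p, penalties, lambda, ridge_lambda) {
  P <- matrix(0, p, p)
  for (pen in penalties) {
    lam <- if (pen$kind == "smooth") lambda else ridge_lambda
    P[pen$idx, pen$idx] <- P[pen$idx, pen$idx] + lam * pen$S
  }
  P
}

softmax_probs <- function(eta) {
  # eta: n x (K-1); reference class prepended with linear predictor 0
  expEta <- exp(cbind(0, eta) - apply(cbind(0, eta), 1, max))
  expEta / rowSums(expEta)
}

#' Fit a penalized multinomial rhythm-probability model
#'
#' Maximizes the multinomial log-likelihood minus quadratic penalties:
#' thin-plate penalties on smooth terms (one shared smoothing parameter)
#' and a ridge penalty on grouping-factor indicator coefficients, both
#' scaled with the number of observations so that duplicating every row
#' leaves the estimates unchanged.  Optimization is full Newton with step
#' halving; convergence requires a gradient sup-norm below `gtol`.
#' Linear separation is reported (with a warning) when coefficients
#' diverge.
#'
#' @param spec A [model_spec()].
#' @param data Data frame containing the response and all covariates;
#'   incomplete rows (on the used columns) are dropped.
#' @param response Response column name (default `"class"`).
#' @param reference Reference class; default `"diel"` when present,
#'   otherwise the most frequent class.
#' @param lambda Smoothing parameter for all smooth terms; `NULL` selects
#'   it by 5-fold cross-validation over `lambda_grid`.
#' @param lambda_grid Candidate smoothing parameters.
#' @param ridge_lambda Ridge rate for group-effect coefficients.
#' @param basis_k Spline basis dimension.
#' @param gtol Gradient sup-norm convergence tolerance.
#' @param maxit Maximum Newton iterations.
#'
#' @return An object of class `rhythm_prob_model` with coefficients,
#'   standard errors, fitted class probabilities, log-likelihood and the
#'   stored design for prediction.
#' @export
fit_multinomial <- function(spec, data, response = "class",
                            reference = NULL,
                            lambda = NULL,
                            lambda_grid = c(0.01, 0.1, 1, 10, 100),
                            ridge_lambda = 0.1,
                            basis_k = 8, gtol = 1e-6, maxit = 200) {
  used <- c(response, intersect(spec_columns(spec), names(data)))
  data <- data[stats::complete.cases(data[, used, drop = FALSE]), ,
               drop = FALSE]
  y <- factor(data[[response]])
  if (nlevels(droplevels(y)) < 2) stop_br("need at least 2 observed classes")
  if (is.null(reference)) {
    reference <- if ("diel" %in% levels(y)) "diel" else
      names(which.max(table(y)))
  }
  y <- stats::relevel(y, ref = reference)
  has_smooth <- any(vapply(spec$terms,
                           function(tm) parse_term(tm)$type == "smooth",
                           TRUE))
  if (is.null(lambda)) {
    lambda <- if (!has_smooth) 1 else
      select_lambda(spec, data, response, reference, lambda_grid,
                    ridge_lambda, basis_k, gtol, maxit)
  }
  design <- build_design(spec, data, basis_k)
  fit <- fit_multinomial_core(design, y, lambda, ridge_lambda, gtol, maxit)
  structure(c(fit, list(spec = spec, reference = reference,
                        classes = levels(y), design = design,
                        lambda = lambda, ridge_lambda = ridge_lambda,
                        response = response, n = nrow(data))),
            class = "rhythm_prob_model")
}

fit_multinomial_core <- function(design, y, lambda, ridge_lambda,
                                 gtol = 1e-6, maxit = 200) {
  X <- design$X
  n <- nrow(X); p <- ncol(X)
  K <- nlevels(y)
  Y <- stats::model.matrix(~ y - 1)[, -1, drop = FALSE]   # n x (K-1)
  Pen <- n * penalty_matrix(p, design$penalties, lambda, ridge_lambda)
  B <- matrix(0, p, K - 1)
  objective <- function(B) {
    P <- softmax_probs(X %*% B)
    ll <- sum(log(pmax(P[cbind(seq_len(n), as.integer(y))], 1e-300)))
    ll - 0.5 * sum(vapply(seq_len(K - 1),
                          function(k) drop(B[, k] %*% Pen %*% B[, k]), 0))
  }
  obj <- objective(B)
  converged <- FALSE
  separated <- FALSE
  grad_norm <- Inf
  for (it in seq_len(maxit)) {
    P <- softmax_probs(X %*% B)
    Pk <- P[, -1, drop = FALSE]
    G <- crossprod(X, Y - Pk) - Pen %*% B          # p x (K-1)
    grad_norm <- max(abs(G))
    if (grad_norm < gtol) { converged <- TRUE; break }
    H <- matrix(0, p * (K - 1), p * (K - 1))
    for (k in seq_len(K - 1)) {
      for (l in k:(K - 1)) {
        w <- Pk[, k] * ((k == l) - Pk[, l])
        Hkl <- -crossprod(X, X * w)
        if (k == l) Hkl <- Hkl - Pen
        ri <- ((k - 1) * p + 1):(k * p)
        ci <- ((l - 1) * p + 1):(l * p)
        H[ri, ci] <- Hkl
        if (k != l) H[ci, ri] <- t(Hkl)
      }
    }
    step <- tryCatch(solve(H, -as.vector(G)),
                     error = function(e) NULL)
    if (is.null(step)) {
      step <- solve(H - diag(1e-8 * n, nrow(H)), -as.vector(G))
    }
    step <- matrix(step, p, K - 1)
    alpha <- 1
    repeat {
      Bn <- B + alpha * step
      on <- objective(Bn)
      if (is.finite(on) && on >= obj - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
    B <- B + alpha * step
    obj <- objective(B)
    if (max(abs(B)) > 30) break
  }
  if (max(abs(B)) > 30) {
    # a linear predictor beyond +-30 pins probabilities to machine 0/1:
    # the likelihood is flat there, so large coefficients signal separation
    separated <- TRUE
    warn_br("possible separation: coefficient magnitudes diverging")
  }
  if (!converged && !separated) {
    warn_br("Newton did not reach gradient tolerance (grad sup-norm ",
            signif(grad_norm, 3), ")")
  }
  P <- softmax_probs(X %*% B)
  colnames(P) <- levels(y)
  # observed penalized information for standard errors
  Pk <- P[, -1, drop = FALSE]
  H <- matrix(0, p * (K - 1), p * (K - 1))
  for (k in seq_len(K - 1)) {
    for (l in k:(K - 1)) {
      w <- Pk[, k] * ((k == l) - Pk[, l])
      Hkl <- crossprod(X, X * w)
      if (k == l) Hkl <- Hkl + Pen
      ri <- ((k - 1) * p + 1):(k * p)
      ci <- ((l - 1) * p + 1):(l * p)
      H[ri, ci] <- Hkl
      if (k != l) H[ci, ri] <- t(Hkl)
    }
  }
  V <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, nrow(H), ncol(H)))
  SE <- matrix(sqrt(pmax(diag(V), 0)), p, K - 1)
  dimnames(B) <- dimnames(SE) <-
    list(colnames(X), levels(y)[-1])
  ll <- sum(log(pmax(P[cbind(seq_len(n), as.integer(y))], 1e-300)))
  list(coefficients = B, se = SE, vcov = V, fitted = P,
       loglik = ll, converged = converged, separated = separated,
       grad_norm = grad_norm)
}

# Choose the shared smoothing parameter by 5-fold CV log score.
select_lambda <- function(spec, data, response, reference, grid,
                          ridge_lambda, basis_k, gtol, maxit) {
  y <- stats::relevel(factor(data[[response]]), ref = reference)
  folds <- fold_assignment(data, n_folds = 5, grouping = NULL, y = y)
  scores <- vapply(grid, function(lam) {
    s <- 0
    for (f in seq_len(max(folds))) {
      tr <- folds != f; te <- !tr
      d <- build_design(spec, data[tr, , drop = FALSE], basis_k)
      fit <- suppressWarnings(
        fit_multinomial_core(d, droplevels_keep(y[tr], levels(y)), lam,
                             ridge_lambda, gtol, maxit = 50))
      Xte <- predict_design(d, data[te, , drop = FALSE])
      P <- softmax_probs(Xte %*% fit$coefficients)
      s <- s + sum(log(pmax(P[cbind(seq_len(sum(te)),
                                    as.integer(y[te]))], 1e-300)))
    }
    s
  }, 0)
  grid[which.max(scores)]
}

droplevels_keep <- function(y, lev) factor(y, levels = lev)

#' Predict rhythm-class probabilities
#'
#' Softmax of the fitted linear predictors on new covariates.  Unseen
#' grouping-factor levels receive the population-level (zero) group
#' effect; unseen levels of fixed categorical predictors are an error.
#'
#' @param model A fitted [fit_multinomial()] model.
#' @param newdata Data frame of covariates.
#'
#' @return Matrix of per-class probabilities (rows sum to 1), columns in
#'   class order (reference first).
#' @export
predict_probs <- function(model, newdata) {
  X <- predict_design(model$design, newdata)
  P <- softmax_probs(X %*% model$coefficients)
  colnames(P) <- model$classes
  P
}

# ---- cross-validation and stacking -----------------------------------------

# Deterministic fold assignment: grouped (all rows of a group share a
# fold, groups dealt round-robin in order of appearance) or stratified by
# class when no grouping column is available.
fold_assignment <- function(data, n_folds, grouping, y) {
  n <- nrow(data)
  if (!is.null(grouping) && grouping %in% names(data)) {
    g <- as.character(data[[grouping]])
    ug <- unique(g)
    if (length(ug) >= n_folds) {
      gf <- ((match(g, ug) - 1L) %% n_folds) + 1L
      return(gf)
    }
  }
  folds <- integer(n)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- ((seq_along(idx) - 1L) %% n_folds) + 1L
  }
  folds
}

#' Cross-validated expected log predictive density
#'
#' K-fold cross-validation of a candidate model: the elpd is the sum over
#' held-out observations of the log predicted probability of the observed
#' class, with a standard error from the pointwise variance.  Folds are
#' grouped by `grouping` (default bear id, so no bear spans folds),
#' falling back to class-stratified folds when the grouping column is
#' absent or has fewer groups than folds.
#'
#' @inheritParams fit_multinomial
#' @param n_folds Number of folds (>= 2), default 10.
#' @param grouping Grouping column for fold assignment.
#'
#' @return List with `elpd`, `se`, `pointwise` (per-observation log
#'   predictive densities, in data order) and `heldout_prob` (held-out
#'   predicted probability of the observed class).
#' @export
cv_elpd <- function(spec, data, response = "class", n_folds = 10,
                    grouping = "bear_id", reference = NULL,
                    lambda = NULL, ridge_lambda = 0.1, basis_k = 8) {
  if (n_folds < 2) stop_br("need at least 2 folds")
  used <- c(response, intersect(spec_columns(spec), names(data)))
  data <- data[stats::complete.cases(data[, used, drop = FALSE]), ,
               drop = FALSE]
  y <- factor(data[[response]])
  if (is.null(reference)) {
    reference <- if ("diel" %in% levels(y)) "diel" else
      names(which.max(table(y)))
  }
  y <- stats::relevel(y, ref = reference)
  folds <- fold_assignment(data, n_folds, grouping, y)
  n <- nrow(data)
  lpd <- numeric(n)
  hp <- numeric(n)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    ytr <- droplevels_keep(y[tr], levels(y))
    if (nlevels(droplevels(ytr)) < nlevels(y)) {
      warn_br("fold ", f, " lacks a class in training; ",
              "its probability is penalized through the model")
    }
    fit <- suppressWarnings(
      fit_multinomial(spec, data[tr, , drop = FALSE], response,
                      reference = reference, lambda = lambda,
                      ridge_lambda = ridge_lambda, basis_k = basis_k))
    P <- predict_probs(fit, data[!tr, , drop = FALSE])
    pobs <- P[cbind(seq_len(sum(!tr)), as.integer(y[!tr]))]
    hp[!tr] <- pobs
    lpd[!tr] <- log(pmax(pobs, 1e-300))
  }
  list(elpd = sum(lpd), se = sqrt(n * stats::var(lpd)),
       pointwise = lpd, heldout_prob = hp, folds = folds)
}

#' Stacking weights for predictive distributions
#'
#' Finds the simplex weights maximizing the summed log of the weighted
#' held-out predictive densities, `sum_i log(sum_m w_m p_mi)` -- a concave
#' problem solved by deterministic multiplicative (EM) updates.  Models
#' with identical predictive densities are collapsed first and the tied
#' weight is split evenly among them.
#'
#' @param heldout_probs Matrix (observations x models) of held-out
#'   predictive probabilities of the observed class, all models scored on
#'   identical observations.  Column names label the models.
#'
#' @return An object of class `stacking_result`: `weights` (non-negative,
#'   summing to 1) and `log_score` of the stacked predictor.
#' @export
stacking_weights <- function(heldout_probs) {
  P <- as.matrix(heldout_probs)
  M <- ncol(P)
  if (is.null(colnames(P))) colnames(P) <- paste0("model", seq_len(M))
  if (M == 1) {
    return(structure(list(weights = stats::setNames(1, colnames(P)),
                          log_score = sum(log(pmax(P[, 1], 1e-300)))),
                     class = "stacking_result"))
  }
  # collapse duplicate predictive distributions
  groups <- integer(M)
  reps <- list()
  for (m in seq_len(M)) {
    hit <- 0L
    for (r in seq_along(reps)) {
      if (max(abs(P[, m] - P[, reps[[r]][1]])) < 1e-10) { hit <- r; break }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1]] <- m
      groups[m] <- length(reps)
    } else {
      reps[[hit]] <- c(reps[[hit]], m)
      groups[m] <- hit
    }
  }
  U <- P[, vapply(reps, `[`, 0L, 1), drop = FALSE]
  U <- pmax(U, 1e-300)
  w <- rep(1 / ncol(U), ncol(U))
  for (it in seq_len(10000)) {
    mix <- as.numeric(U %*% w)
    w_new <- w * colMeans(U / mix)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < 1e-12) { w <- w_new; break }
    w <- w_new
  }
  weights <- numeric(M)
  for (r in seq_along(reps)) {
    weights[reps[[r]]] <- w[r] / length(reps[[r]])
  }
  names(weights) <- colnames(P)
  structure(list(weights = weights,
                 log_score = sum(log(as.numeric(P %*% weights)))),
            class = "stacking_result")
}

#' Compare candidate models by cross-validated elpd and stacking
#'
#' Cross-validates every candidate, ranks them by elpd, and computes
#' stacking weights among the models whose elpd lies within
#' `elpd_window` of the best (others receive weight zero), mirroring the
#' practice of stacking only models of comparable predictive accuracy.
#'
#' @inheritParams cv_elpd
#' @param specs Named list of [model_spec()] objects.
#' @param elpd_window Elpd difference below which models are considered
#'   comparable (default 4).
#'
#' @return List with `table` (name, elpd, se, delta_elpd, stacking
#'   weight; ordered by rank) and `stacking` (the [stacking_weights()]
#'   result over the comparable set).
#' @export
compare_models <- function(specs, data, response = "class", n_folds = 10,
                           grouping = "bear_id", reference = NULL,
                           lambda = NULL, ridge_lambda = 0.1,
                           basis_k = 8, elpd_window = 4) {
  cvs <- lapply(specs, cv_elpd, data = data, response = response,
                n_folds = n_folds, grouping = grouping,
                reference = reference, lambda = lambda,
                ridge_lambda = ridge_lambda, basis_k = basis_k)
  elpd <- vapply(cvs, `[[`, 0, "elpd")
  se <- vapply(cvs, `[[`, 0, "se")
  delta <- max(elpd) - elpd
  close <- delta < elpd_window
  hp <- do.call(cbind, lapply(cvs[close], `[[`, "heldout_prob"))
  colnames(hp) <- names(specs)[close]
  st <- stacking_weights(hp)
  weight <- stats::setNames(numeric(length(specs)), names(specs))
  weight[names(st$weights)] <- st$weights
  tab <- data.frame(model = names(specs), elpd = elpd, se = se,
                    delta_elpd = delta, stacking_weight = weight,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$elpd), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, stacking = st, cv = cvs)
}
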