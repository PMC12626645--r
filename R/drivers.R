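#' Keystone importance by ensemble regression with permutation significance
#'
#' Random-forest regression of a per-sample stability response on keystone
#' abundances. Importance is the out-of-bag %IncMSE (increase in mean squared
#' error when the predictor is permuted). Significance comes from refitting
#' the forest under `n_perm` response permutations:
#' `p = (1 + #permuted importance >= observed) / (1 + n_perm)`.
#'
#' @param X samples-by-keystone abundance matrix or data frame (>= 1 column).
#' @param y per-sample stability response (length >= 10, non-constant).
#' @param n_trees trees per forest.
#' @param n_perm response permutations for the p-value.
#' @param seed integer seed, or NULL.
#' @return tibble: taxon, inc_mse_pct, p_value.
#' @export
keystone_importance <- function(X, y, n_trees = 500, n_perm = 100,
                                seed = NULL) {
  X <- as.data.frame(X)
  if (ncol(X) < 1) {
    abort("need at least one keystone column.",
          class = "netstab_invalid_input")
  }
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (length(y) < 10) {
    abort("keystone importance needs >= 10 samples.",
          class = "netstab_invalid_input")
  }
  if (sd(y) == 0) {
    abort("response is constant.", class = "netstab_invalid_input")
  }
  check_scalar(n_trees, "n_trees", 1, Inf, TRUE)
  check_scalar(n_perm, "n_perm", 1, Inf, TRUE)
  imp_of <- function(yy) {
    rf <- randomForest::randomForest(x = X, y = yy, ntree = n_trees,
                                     importance = TRUE)
    randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
  }
  with_seed(seed, {
    obs <- imp_of(y)
    exceed <- rep(0, length(obs))
    for (i in seq_len(n_perm)) {
      exceed <- exceed + (imp_of(sample(y)) >= obs)
    }
    tibble(taxon = colnames(X), inc_mse_pct = unname(obs),
           p_value = unname((1 + exceed) / (1 + n_perm))) |>
      dplyr::arrange(dplyr::desc(.data$inc_mse_pct))
  })
}

adj_r2 <- function(fit, n) {
  s <- summary(fit)
  s$adj.r.squared
}

#' Forward selection of environmental variables
#'
#' Greedy stepwise construction of a linear model for the response: at each
#' step the candidate with the largest adjusted-R^2 gain is tried and accepted
#' only if the gain is positive and its permutation p-value (response rows
#' permuted against the design, gain recomputed) is at or below `alpha`.
#' Collinear candidates (aliased coefficients) are skipped with a warning.
#'
#' @param env data frame of numeric candidate variables (a sample id column
#'   is ignored); >= 2 candidates, and n > candidates + 2.
#' @param response per-sample numeric response.
#' @param alpha acceptance level for the permutation test.
#' @param n_perm permutations per tested variable.
#' @param seed integer seed, or NULL.
#' @return tibble of accepted variables in selection order: variable,
#'   adj_r2 (cumulative), gain, p_value. Zero rows when nothing qualifies.
#' @export
forward_select <- function(env, response, alpha = 0.05, n_perm = 999,
                           seed = NULL) {
  env <- as.data.frame(env)
  env <- env[, !(names(env) %in% c("sample_id", "sample")), drop = FALSE]
  num <- vapply(env, is.numeric, TRUE)
  env <- env[, num, drop = FALSE]
  if (ncol(env) < 2) {
    abort("need >= 2 candidate variables.", class = "netstab_invalid_input")
  }
  n <- length(response)
  if (n != nrow(env) || n <= ncol(env) + 2) {
    abort("need n > candidates + 2 with matching lengths.",
          class = "netstab_invalid_input")
  }
  check_scalar(alpha, "alpha", 0, 1)
  check_scalar(n_perm, "n_perm", 1, Inf, TRUE)
  dat <- cbind(.response = response, env)
  selected <- character()
  current_r2 <- 0  # adjusted R2 of the intercept-only model
  out <- tibble(variable = character(), adj_r2 = numeric(),
                gain = numeric(), p_value = numeric())
  with_seed(seed, {
    repeat {
      candidates <- setdiff(names(env), selected)
      if (!length(candidates)) break
      gains <- vapply(candidates, function(v) {
        f <- as.formula(paste(".response ~",
                              paste(c(selected, v), collapse = " + ")))
        fit <- lm(f, data = dat)
        if (anyNA(coef(fit))) return(NA_real_)  # collinear: skip
        adj_r2(fit) - current_r2
      }, numeric(1))
      if (any(is.na(gains))) {
        warn(paste0("collinear candidate(s) skipped: ",
                    paste(candidates[is.na(gains)], collapse = ", ")))
      }
      if (all(is.na(gains)) || max(gains, na.rm = TRUE) <= 0) break
      best <- candidates[which.max(gains)]  # ties: first in column order
      obs_gain <- gains[[best]]
      f_best <- paste(c(selected, best), collapse = " + ")
      perm_gain <- vapply(seq_len(n_perm), function(i) {
        dperm <- dat
        dperm$.response <- dat$.response[sample.int(n)]
        base_r2 <- if (length(selected)) {
          adj_r2(lm(as.formula(paste(".response ~",
                                     paste(selected, collapse = " + "))),
                    data = dperm))
        } else 0
        fit <- lm(as.formula(paste(".response ~", f_best)), data = dperm)
        adj_r2(fit) - base_r2
      }, numeric(1))
      p <- (1 + sum(perm_gain >= obs_gain)) / (1 + n_perm)
      if (p > alpha) break
      selected <- c(selected, best)
      current_r2 <- current_r2 + obs_gain
      out <- dplyr::bind_rows(out, tibble(variable = best,
                                          adj_r2 = current_r2,
                                          gain = obs_gain, p_value = p))
    }
  })
  out
}

#' Fit a standardized linear path model
#'
#' Each equation is fit by ordinary least squares on z-scored variables, so
#' coefficients are standardized path weights; a single-predictor equation's
#' coefficient equals the sample correlation. Direct, indirect (sum over all
#' directed paths of the product of coefficients along the path) and total
#' effects are decomposed for every connected source-sink pair.
#'
#' @param formulas list of model formulas (`response ~ predictors`), one per
#'   endogenous variable; jointly acyclic.
#' @param data data frame containing every variable.
#' @param standardize z-score variables before fitting (default TRUE).
#' @return `path_model`: coefficient tibble, per-equation R^2, effects table.
#' @export
fit_path_model <- function(formulas, data, standardize = TRUE) {
  if (inherits(formulas, "formula")) formulas <- list(formulas)
  edges <- purrr::map_dfr(formulas, function(f) {
    tt <- terms(f)
    resp <- all.vars(f)[1]
    preds <- attr(tt, "term.labels")
    tibble(from = preds, to = resp)
  })
  resp_vars <- purrr::map_chr(formulas, ~ all.vars(.x)[1])
  if (anyDuplicated(resp_vars)) {
    abort("each endogenous variable may appear as response only once.",
          class = "netstab_invalid_argument")
  }
  vars <- union(edges$from, edges$to)
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    abort(paste0("variables absent from data: ",
                 paste(missing, collapse = ", ")),
          class = "netstab_invalid_input")
  }
  topo_order(edges)  # errors on cycles, naming the offenders
  dat <- as.data.frame(data)[, vars, drop = FALSE]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  max_preds <- max(table(edges$to))
  if (n <= max_preds + 2) {
    abort("too few complete samples for the largest equation.",
          class = "netstab_invalid_input")
  }
  if (standardize) {
    dat[] <- lapply(dat, function(col) {
      s <- sd(col)
      if (s > 0) (col - mean(col)) / s else col - mean(col)
    })
  }
  coefs <- tibble()
  r2 <- tibble()
  beta <- matrix(0, length(vars), length(vars),
                 dimnames = list(vars, vars))  # beta[from, to]
  for (f in formulas) {
    resp <- all.vars(f)[1]
    fit <- lm(f, data = dat)
    sm <- summary(fit)
    ct <- sm$coefficients
    preds <- rownames(ct)[rownames(ct) != "(Intercept)"]
    coefs <- dplyr::bind_rows(coefs, tibble(
      response = resp, predictor = preds,
      estimate = ct[preds, 1], std_error = ct[preds, 2],
      statistic = ct[preds, 3], p_value = ct[preds, 4]
    ))
    beta[preds, resp] <- ct[preds, 1]
    r2 <- dplyr::bind_rows(r2, tibble(response = resp,
                                      r_squared = sm$r.squared,
                                      adj_r_squared = sm$adj.r.squared))
  }
  effects <- decompose_effects(beta)
  structure(list(coefficients = coefs, r2 = r2, effects = effects,
                 beta = beta, n = n, formulas = formulas),
            class = "path_model")
}

# enumerate all directed paths of a DAG coefficient matrix and decompose
# effects: direct = edge coefficient, indirect = sum over paths of length >= 2
# of the product of coefficients, total = direct + indirect
decompose_effects <- function(beta) {
  vars <- rownames(beta)
  out <- tibble()
  for (src in vars) {
    # DFS over paths from src
    acc <- new.env(parent = emptyenv())
    walk <- function(node, prod, len) {
      for (nxt in vars[beta[node, ] != 0]) {
        contrib <- prod * beta[node, nxt]
        key <- nxt
        rec <- get0(key, envir = acc, ifnotfound = c(direct = 0, indirect = 0))
        if (len == 0) rec["direct"] <- rec["direct"] + contrib
        else rec["indirect"] <- rec["indirect"] + contrib
        assign(key, rec, envir = acc)
        walk(nxt, contrib, len + 1)
      }
    }
    walk(src, 1, 0)
    for (snk in ls(acc)) {
      rec <- get(snk, envir = acc)
      out <- dplyr::bind_rows(out, tibble(
        source = src, sink = snk,
        direct = unname(rec["direct"]), indirect = unname(rec["indirect"]),
        total = unname(rec["direct"] + rec["indirect"])
      ))
    }
  }
  out
}

#' @export
print.path_model <- function(x, ...) {
  cat("Standardized path model (", nrow(x$r2), "equations, n =", x$n, ")\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.path_model <- function(x, ...) x$coefficients

#' @export
glance.path_model <- function(x, ...) x$r2
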