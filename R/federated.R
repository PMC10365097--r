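#' Configuration for the federated solver
#'
#' @param learning_rate Gradient-descent step size applied to the mean-loss
#'   gradient on standardized data. Default 0.1.
#' @param max_iterations Iteration cap. Default 10000.
#' @param tolerance Stopping rule: global mean-loss gradient norm. Default 1e-8.
#' @param n_sites Number of hypothetical institutions when the caller
#'   partitions data itself. Default 1.
#' @param seed Seed for any randomized step (site partitioning). Default 1.
#' @return A `federated_config` list.
#' @export
federated_config <- function(learning_rate = 0.1, max_iterations = 10000L,
                             tolerance = 1e-8, n_sites = 1L, seed = 1L) {
  stopifnot(learning_rate > 0, max_iterations >= 1, tolerance > 0, n_sites >= 1)
  structure(list(learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 n_sites = as.integer(n_sites),
                 seed = as.integer(seed)),
            class = "federated_config")
}

#' Per-institution data holder
#'
#' One institution's samples: biomarker values, expression values and the
#' genotype subgroup label of each sample. A site may hold zero samples of
#' some subgroup.
#'
#' @param site_id Identifier of the institution.
#' @param x Numeric biomarker vector.
#' @param y Numeric expression vector, same length.
#' @param group_labels Subgroup label per sample (coerced to character).
#' @return A `site_data` object.
#' @export
site_data <- function(site_id, x, y, group_labels) {
  x <- as.numeric(x); y <- as.numeric(y)
  g <- as.character(group_labels)
  if (length(x) != length(y) || length(x) != length(g))
    stop_fedchow("x, y and group_labels must have equal length", "fedchow_invalid")
  structure(list(site_id = site_id, x = x, y = y, group_labels = g),
            class = "site_data")
}

site_index <- function(site, group) {
  if (identical(group, "combined")) seq_along(site$x)
  else which(site$group_labels == group)
}

#' Local gradient of the least-squares loss at one site
#'
#' Computes the site's contribution to the global gradient,
#' `t(X) %*% (X w - y)` with `X = [1, x]` restricted to the site's samples in
#' the requested subgroup (`"combined"` = all samples). This vector, together
#' with scalar residual sums and counts, is the only thing a site ever emits.
#'
#' @param w Current coefficient vector (length 2, intercept first).
#' @param site A [site_data] object.
#' @param group Subgroup label, or `"combined"`.
#' @return A `gradient_message`: list with `site_id`, `group`, `type`,
#'   `gradient` and `n_samples`. Sites with no samples in the subgroup emit a
#'   zero gradient with `n_samples = 0`.
#' @export
local_gradient <- function(w, site, group = "combined") {
  if (length(w) != 2L)
    stop_fedchow("w must have length 2 (intercept, slope)", "fedchow_invalid")
  idx <- site_index(site, group)
  if (length(idx) == 0L) {
    grad <- c(0, 0)
  } else {
    X <- cbind(1, site$x[idx])
    grad <- as.numeric(crossprod(X, X %*% w - site$y[idx]))
  }
  structure(list(site_id = site$site_id, group = group, type = "gradient",
                 gradient = grad, n_samples = length(idx)),
            class = "gradient_message")
}

#' Sum gradient messages into the global gradient
#'
#' @param messages List of gradient messages, one per site, for one subgroup.
#' @return List with the summed `gradient` and total `n_samples`.
#' @export
aggregate_gradients <- function(messages) {
  lens <- vapply(messages, function(m) length(m$gradient), 0L)
  if (length(unique(lens)) != 1L)
    stop_fedchow("gradient messages have mismatched lengths (protocol corruption)",
                 "fedchow_protocol")
  list(gradient = Reduce(`+`, lapply(messages, `[[`, "gradient")),
       n_samples = as.integer(sum(vapply(messages,
                                         function(m) as.numeric(m$n_samples),
                                         0))))
}

#' One coordinator round: aggregate site gradients and step the coefficients
#'
#' The coordinator sums the per-site gradients and broadcasts the sum; each
#' site then applies the identical update `w <- w - eta * grad / N` (the
#' mean-loss gradient, so the step size is sample-size free). The coordinator
#' itself never holds an updated `w`; this function returns the update every
#' site computes from the broadcast.
#'
#' @param messages List of gradient messages covering all sites for one group.
#' @param w Current coefficient vector.
#' @param config A [federated_config].
#' @return Updated coefficient vector.
#' @export
aggregate_and_step <- function(messages, w, config = federated_config()) {
  agg <- aggregate_gradients(messages)
  w - config$learning_rate * agg$gradient / max(1L, agg$n_samples)
}

# ---- transcript -------------------------------------------------------------

new_transcript <- function() {
  e <- new.env(parent = emptyenv())
  e$msgs <- list()
  e
}

log_msg <- function(tr, site_id, group, type, payload) {
  if (is.null(tr)) return(invisible(NULL))
  tr$msgs[[length(tr$msgs) + 1L]] <-
    list(site_id = site_id, group = group, type = type, payload = payload)
  invisible(NULL)
}

#' Serialize a federated message transcript as newline-delimited JSON
#'
#' @param transcript A transcript list as attached to [federated_chow] results
#'   (attribute `"transcript"`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(transcript, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in transcript)
    writeLines(jsonlite::toJSON(m, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

# ---- solver core ------------------------------------------------------------

# Gradient descent on standardized normal-equation aggregates.
# A: 2x2 aggregated crossprod; B: 2xG aggregated t(X) %*% Y; N: total samples.
# Identical to summing per-site gradients each round, since
# sum_i (A_i w - b_i) = A w - b.
fed_gd_solve <- function(A, B, N, config) {
  B <- as.matrix(B)
  W <- matrix(0, nrow = 2L, ncol = ncol(B))
  lr <- config$learning_rate
  it <- 0L
  gn <- Inf
  while (it < config$max_iterations) {
    Gr <- A %*% W - B
    gn <- sqrt(max(colSums(Gr^2))) / N
    if (gn < config$tolerance) break
    W <- W - (lr / N) * Gr
    it <- it + 1L
  }
  list(W = W, n_iter = it, grad_norm = gn,
       converged = gn < config$tolerance)
}

# per-site standardized moments for one group
site_moments <- function(site, group) {
  idx <- site_index(site, group)
  x <- site$x[idx]; y <- site$y[idx]
  c(n = length(idx), sum_x = sum(x), sum_x2 = sum(x^2),
    sum_y = sum(y), sum_y2 = sum(y^2))
}

#' Federated least-squares fit of one subgroup across institutions
#'
#' Implements the multi-site fitting loop: sites first report count-level
#' moments (n, sums, sums of squares) so all sites can standardize against the
#' global mean and variance; gradient descent then iterates with the
#' coordinator aggregating per-site gradients and broadcasting the sum until
#' the global mean-loss gradient norm drops below `config$tolerance`. Finally
#' each site reports its residual sum of squares and count on the original
#' scale, and the coordinator sums them. Raw sample values never leave a site.
#'
#' @param sites List of [site_data] objects.
#' @param group Subgroup label to fit, or `"combined"` for all samples.
#' @param config A [federated_config].
#' @param transcript Optional transcript environment (internal; use
#'   [federated_chow]`(log_transcript = TRUE)` to obtain message logs).
#' @return A [regression_fit] with original-scale coefficients, the summed
#'   per-site `rss` and total `n_samples`. Non-convergence at the iteration
#'   cap is flagged (`converged = FALSE`) with a warning, not an error.
#' @export
federated_ols <- function(sites, group = "combined",
                          config = federated_config(), transcript = NULL) {
  mom <- lapply(sites, site_moments, group = group)
  for (i in seq_along(sites))
    log_msg(transcript, sites[[i]]$site_id, group, "moments", mom[[i]])
  tot <- Reduce(`+`, mom)
  n <- tot[["n"]]
  if (n < 3L)
    stop_fedchow(sprintf("subgroup '%s' has %d samples; need at least 3", group, n),
                 "fedchow_unfittable")
  mx <- tot[["sum_x"]] / n
  my <- tot[["sum_y"]] / n
  vx <- (tot[["sum_x2"]] - n * mx^2) / (n - 1)
  vy <- (tot[["sum_y2"]] - n * my^2) / (n - 1)
  if (vx <= 0)
    stop_fedchow(sprintf("subgroup '%s' has a constant biomarker", group),
                 "fedchow_unfittable")
  sx <- sqrt(vx)
  sy <- if (vy > 0) sqrt(vy) else 1   # constant y: fit the zero function
  # sites standardize locally against the global moments and cache crossprods;
  # the cached A_i, b_i reproduce X_i'(X_i w - y_i) exactly at every round
  Ab <- lapply(sites, function(s) {
    idx <- site_index(s, group)
    xs <- (s$x[idx] - mx) / sx
    ys <- (s$y[idx] - my) / sy
    X <- cbind(1, xs)
    list(A = crossprod(X), b = crossprod(X, ys))
  })
  if (is.null(transcript)) {
    A <- Reduce(`+`, lapply(Ab, `[[`, "A"))
    b <- Reduce(`+`, lapply(Ab, `[[`, "b"))
    sol <- fed_gd_solve(A, b, n, config)
    w_std <- sol$W[, 1L]
  } else {
    # explicit message exchange, one gradient message per site per round
    w_std <- c(0, 0)
    it <- 0L; gn <- Inf
    while (it < config$max_iterations) {
      msgs <- lapply(seq_along(sites), function(i) {
        g <- as.numeric(Ab[[i]]$A %*% w_std - Ab[[i]]$b)
        m <- structure(list(site_id = sites[[i]]$site_id, group = group,
                            type = "gradient", gradient = g,
                            n_samples = unname(mom[[i]]["n"])),
                       class = "gradient_message")
        log_msg(transcript, m$site_id, group, "gradient", g)
        m
      })
      agg <- aggregate_gradients(msgs)
      gn <- sqrt(sum(agg$gradient^2)) / n
      log_msg(transcript, "coordinator", group, "global_gradient", agg$gradient)
      if (gn < config$tolerance) break
      w_std <- w_std - config$learning_rate * agg$gradient / n
      it <- it + 1L
    }
    sol <- list(n_iter = it, grad_norm = gn, converged = gn < config$tolerance)
  }
  if (!sol$converged)
    warning(sprintf(
      "federated solve for subgroup '%s' hit max_iterations (gradient norm %.3g)",
      group, sol$grad_norm))
  # back-transform to the original scale
  slope <- w_std[2L] * sy / sx
  intercept <- my + sy * w_std[1L] - slope * mx
  # each site evaluates its residual sum on the original scale; only the
  # scalar S_i and count N_i are reported
  rss_n <- vapply(sites, function(s) {
    idx <- site_index(s, group)
    r <- s$y[idx] - (intercept + slope * s$x[idx])
    c(rss = sum(r^2), n = length(idx))
  }, c(rss = 0, n = 0))
  for (i in seq_along(sites))
    log_msg(transcript, sites[[i]]$site_id, group, "rss",
            c(rss = unname(rss_n["rss", i]), n_samples = unname(rss_n["n", i])))
  regression_fit(coefficients = c(intercept, slope),
                 rss = sum(rss_n["rss", ]),
                 n_samples = n,
                 converged = sol$converged,
                 grad_norm = sol$grad_norm,
                 n_iter = sol$n_iter)
}

# subgroup labels with at least min_n samples pooled across sites, sorted
eligible_groups <- function(sites, min_n = 3L) {
  labs <- sort(unique(unlist(lapply(sites, `[[`, "group_labels"))))
  labs <- labs[!is.na(labs)]
  n_by <- vapply(labs, function(g)
    sum(vapply(sites, function(s) sum(s$group_labels == g), 0L)), 0L)
  labs[n_by >= min_n]
}

chow_na_result <- function(reason) {
  structure(list(f_value = NA_real_, df_num = NA_integer_,
                 df_den = NA_integer_, p_value = NA_real_,
                 group_fits = list(), combined_fit = NULL,
                 n_groups = 0L),
            class = "chow_result", reason = reason)
}

#' Federated generalized Chow test across institutions
#'
#' Runs [federated_ols] once per eligible subgroup and once for the pooled
#' samples of those subgroups (four models when three subgroups are present),
#' then computes the Chow F statistic and p-value at the coordinator from the
#' aggregated residual sums and counts alone. Subgroups with fewer than 3
#' pooled samples (k + 1 with k = 2 parameters) are dropped; if fewer than two
#' eligible subgroups remain the result carries `NA` F and p rather than an
#' error, so genome-scale scans can proceed past degenerate stratifiers.
#'
#' @param sites List of [site_data] objects.
#' @param config A [federated_config].
#' @param log_transcript If `TRUE`, attach the full message log (attribute
#'   `"transcript"`) for privacy auditing; see [write_transcript].
#' @return A `chow_result` (possibly with `NA` p-value). Group labels used are
#'   attached as attribute `"groups"`.
#' @examples
#' set.seed(42)
#' x <- rnorm(90); g <- rep(1:3, each = 30)
#' y <- ifelse(g == 3, 3 * x, 0.5 * x) + rnorm(90, sd = 0.2)
#' s <- partition_sites(x, y, g, n_sites = 3, seed = 1)
#' federated_chow(s)
#' @export
federated_chow <- function(sites, config = federated_config(),
                           log_transcript = FALSE) {
  tr <- if (log_transcript) new_transcript() else NULL
  groups <- eligible_groups(sites)
  fits <- list()
  kept <- character()
  for (g in groups) {
    f <- tryCatch(federated_ols(sites, g, config, transcript = tr),
                  fedchow_unfittable = function(e) NULL)
    if (!is.null(f)) { fits[[g]] <- f; kept <- c(kept, g) }
  }
  if (length(kept) < 2L) {
    res <- chow_na_result("fewer than 2 fittable subgroups")
  } else {
    # pool only the samples belonging to fittable subgroups
    pooled <- lapply(sites, function(s) {
      idx <- which(s$group_labels %in% kept)
      site_data(s$site_id, s$x[idx], s$y[idx], s$group_labels[idx])
    })
    res <- tryCatch({
      comb <- federated_ols(pooled, "combined", config, transcript = tr)
      chow_test(fits, comb)
    }, fedchow_unfittable = function(e) chow_na_result(conditionMessage(e)),
       fedchow_insufficient = function(e) chow_na_result(conditionMessage(e)))
  }
  attr(res, "groups") <- kept
  if (log_transcript) attr(res, "transcript") <- tr$msgs
  res
}
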