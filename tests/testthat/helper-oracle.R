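# Independent brute-force reference implementations, written as straight-line
# lookups and loops. They share only the package's stated conventions (tie
# rules, seed use), never its code paths.

oracle_lagged_rows <- function(daily, direction, T,
                               require_confounders = TRUE,
                               confounder_timing = "before_outcome") {
  conf_num <- c("stress", "energy", "focus", "activity_minutes", "mean_temp",
                "clear_sky_minutes")
  out <- list()
  for (sid in unique(daily$subject_id)) {
    d <- daily[daily$subject_id == sid, ]
    look <- function(day, field) {
      i <- which(d$day_index == day)
      if (!length(i)) return(NA)
      d[[field]][i]
    }
    for (t in sort(d$day_index)) {
      if (direction == "sleep_to_mood") {
        tr <- look(t, "sleep_quality"); outv <- look(t, "mood"); oday <- t
        confday <- t - 1
      } else {
        tr <- look(t, "mood"); outv <- look(t + 1, "sleep_quality"); oday <- t + 1
        confday <- if (confounder_timing == "before_outcome") t else t - 1
      }
      if (is.na(tr) || is.na(outv)) next
      row <- list(subject_id = sid, outcome_day = oday,
                  treatment = as.numeric(tr), outcome = as.numeric(outv))
      ok <- TRUE
      if (require_confounders) {
        for (v in conf_num) {
          val <- look(confday, v)
          if (is.na(val)) { ok <- FALSE; break }
          row[[v]] <- as.numeric(val)
        }
        if (ok) {
          dow <- look(confday, "day_of_week"); dt <- look(confday, "day_type")
          if (is.na(dow) || is.na(dt)) ok <- FALSE
          row$day_of_week <- dow; row$day_type <- dt
        }
        if (ok && T > 0) {
          for (k in seq_len(T)) {
            ml <- look(t - k, "mood"); sl <- look(t - k, "sleep_quality")
            if (is.na(ml) || is.na(sl)) { ok <- FALSE; break }
            row[[paste0("mood_lag", k)]] <- as.numeric(ml)
            row[[paste0("sleep_lag", k)]] <- as.numeric(sl)
          }
        }
      }
      if (ok) out[[length(out) + 1L]] <- tibble::as_tibble(row)
    }
  }
  if (!length(out)) return(tibble::tibble(subject_id = character()))
  dplyr::bind_rows(out)
}

# penalized logistic by general-purpose optimizer (independent of the
# package's Newton iteration); intercept unpenalized, X pre-standardized
oracle_ridge_logit <- function(X, y, lambda) {
  Xd <- cbind(1, X)
  negll <- function(b) {
    eta <- drop(Xd %*% b)
    -sum(y * eta - log1p(exp(eta))) + 0.5 * lambda * sum(b[-1]^2)
  }
  gr <- function(b) {
    mu <- stats::plogis(drop(Xd %*% b))
    -drop(crossprod(Xd, y - mu)) + lambda * c(0, b[-1])
  }
  o <- stats::optim(rep(0, ncol(Xd)), negll, gr, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-14))
  o$par
}

oracle_design <- function(rows) {
  conf_num <- c("stress", "energy", "focus", "activity_minutes", "mean_temp",
                "clear_sky_minutes")
  X <- as.matrix(rows[, conf_num])
  for (lc in grep("^(mood|sleep)_lag[0-9]+$", names(rows), value = TRUE))
    X <- cbind(X, rows[[lc]])
  for (v in c("day_of_week", "day_type")) {
    levs <- sort(unique(as.character(rows[[v]])))
    for (lv in levs[-1]) X <- cbind(X, as.numeric(as.character(rows[[v]]) == lv))
  }
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  if (!ncol(X)) return(NULL)
  sweep(sweep(X, 2, colMeans(X)), 2, apply(X, 2, stats::sd), "/")
}

# the full per-subject chain, brute force
oracle_subject_effect <- function(rows, seed, caliper = 0.2,
                                  caliper_scale = "sd_logit", ridge = 1) {
  tr <- as.integer(rows$treatment > mean(rows$treatment))
  if (!any(tr == 1L) || !any(tr == 0L))
    return(list(effect = NA_real_, reason = "single_class"))
  if (min(sum(tr == 1L), sum(tr == 0L)) < 2L)
    return(list(effect = NA_real_, reason = "too_few_per_class"))
  X <- oracle_design(rows)
  scores <- if (is.null(X)) rep(mean(tr), length(tr)) else
    stats::plogis(drop(cbind(1, X) %*% oracle_ridge_logit(X, tr, ridge)))
  scores <- pmin(1 - 1e-8, pmax(1e-8, scores))
  lg <- stats::qlogis(scores)
  cal <- if (is.null(caliper)) Inf else if (caliper_scale == "logit") caliper
  else { s <- stats::sd(lg); if (is.na(s) || s == 0) Inf else caliper * s }
  t_idx <- which(tr == 1L); c_left <- which(tr == 0L)
  order_t <- if (length(t_idx) == 1L) t_idx else
    withr::with_seed(as.integer(seed), sample(t_idx))
  pt <- pc <- integer(0)
  for (ti in order_t) {
    if (!length(c_left)) break
    dd <- abs(lg[c_left] - lg[ti])
    j <- which.min(dd)
    if (dd[j] <= cal) {
      pt <- c(pt, ti); pc <- c(pc, c_left[j])
      c_left <- c_left[-j]
    }
  }
  if (!length(pt)) return(list(effect = NA_real_, reason = "no_match"))
  y1 <- rows$outcome[pt]; y0 <- rows$outcome[pc]
  n1 <- length(y1); n0 <- length(y0)
  if (n1 + n0 < 3L) return(list(effect = NA_real_, reason = "degenerate_outcome"))
  sp <- sqrt(((n1 - 1) * stats::var(y1) + (n0 - 1) * stats::var(y0)) /
               (n1 + n0 - 2))
  if (!is.finite(sp) || sp == 0)
    return(list(effect = NA_real_, reason = "degenerate_outcome"))
  list(effect = (mean(y1) - mean(y0)) / sp, reason = NA_character_,
       n_pairs = n1)
}

# maximum attainable pair count under a caliper: augmenting-path bipartite
# matching on the admissibility graph
oracle_max_pairs <- function(lg, tr, cal) {
  t_idx <- which(tr == 1L); c_idx <- which(tr == 0L)
  if (!length(t_idx) || !length(c_idx)) return(0L)
  adj <- lapply(t_idx, function(ti) which(abs(lg[c_idx] - lg[ti]) <= cal))
  match_c <- rep(0L, length(c_idx))
  try_aug <- function(i, env) {
    for (j in adj[[i]]) {
      if (env$seen[j]) next
      env$seen[j] <- TRUE
      if (match_c[j] == 0L || try_aug(match_c[j], env)) {
        match_c[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  n <- 0L
  for (i in seq_along(t_idx)) {
    env <- new.env()
    env$seen <- rep(FALSE, length(c_idx))
    if (try_aug(i, env)) n <- n + 1L
  }
  n
}
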