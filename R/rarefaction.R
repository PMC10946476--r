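#' @title Incidence-based rarefaction and extrapolation
#' @name rarefaction
#' @description
#' Sampling completeness per habitat is assessed with sample-based
#' interpolation and extrapolation of richness (Hill number order q = 0,
#' incidence-frequency data). The sampling unit is one blood meal, so the
#' incidence frequency of a host or Diptera taxon is the number of meals
#' involving it and that of an interaction is its link weight. Asymptotic
#' richness uses the Chao2 estimator.
NULL

#' Construct incidence data
#'
#' @param Y named vector of incidence frequencies (meals per taxon/link).
#' @param T total number of sampling units (blood meals).
#' @param entity `"host"`, `"diptera"` or `"interaction"`.
#' @param habitat habitat label.
#' @return object of class `incidence_data` with fields `Y`, `T`, `S_obs`,
#'   `entity`, `habitat`.
#' @export
incidence_data <- function(Y, T = sum(Y), entity = "interaction",
                           habitat = NA_character_) {
  Y <- Y[Y > 0]
  if (any(Y > T)) stop("incidence frequency exceeds the number of units")
  structure(list(entity = entity, habitat = habitat, T = as.integer(T),
                 Y = Y, S_obs = length(Y)),
            class = "incidence_data")
}

#' Incidence frequencies per habitat from a network set
#'
#' Pools the networks of each habitat and counts, per taxon or link, the
#' number of blood meals in which it occurs. `T` is the habitat's total
#' meal count.
#'
#' @param networks a `network_set` or list of `interaction_matrix`.
#' @param entity `"host"`, `"diptera"` or `"interaction"`.
#' @return named list of `incidence_data`, one per habitat present.
#' @export
incidence_from_networks <- function(networks,
                                    entity = c("interaction", "host",
                                               "diptera")) {
  entity <- match.arg(entity)
  nets <- if (inherits(networks, "network_set")) networks$networks
          else networks
  habs <- vapply(nets, `[[`, character(1), "habitat")
  out <- list()
  for (h in unique(habs)) {
    sub <- nets[habs == h]
    acc <- new.env(parent = emptyenv())
    total <- 0L
    for (n in sub) {
      w <- n$weights
      total <- total + sum(w)
      if (entity == "interaction") {
        idx <- which(w > 0, arr.ind = TRUE)
        keys <- paste(rownames(w)[idx[, 1]], colnames(w)[idx[, 2]],
                      sep = " -- ")
        vals <- w[idx]
      } else if (entity == "diptera") {
        keys <- rownames(w)
        vals <- rowSums(w)
      } else {
        keys <- colnames(w)
        vals <- colSums(w)
      }
      vals <- unname(vals)
      for (i in seq_along(keys)) {
        if (vals[i] > 0)
          assign(keys[i], vals[i] + mget(keys[i], acc, ifnotfound = 0)[[1]],
                 envir = acc)
      }
    }
    if (total == 0L) {
      warning("habitat ", h, " has zero blood meals; omitted")
      next
    }
    Y <- unlist(as.list(acc))
    out[[h]] <- incidence_data(Y[sort(names(Y), method = "radix")],
                               T = total, entity = entity, habitat = h)
  }
  out
}

#' Chao2 asymptotic richness
#'
#' S_obs + ((T-1)/T) Q1^2 / (2 Q2) when doubletons exist, else the
#' bias-corrected form S_obs + ((T-1)/T) Q1 (Q1 - 1) / 2, with Q1 and Q2
#' the numbers of taxa seen in exactly one and two sampling units.
#'
#' @param data an `incidence_data`.
#' @return asymptotic richness estimate (never below `S_obs`).
#' @export
chao2 <- function(data) {
  stopifnot(inherits(data, "incidence_data"))
  if (data$T < 2) stop("chao2 needs at least two sampling units")
  Q1 <- sum(data$Y == 1)
  Q2 <- sum(data$Y == 2)
  corr <- (data$T - 1) / data$T
  if (Q2 > 0) data$S_obs + corr * Q1^2 / (2 * Q2)
  else data$S_obs + corr * Q1 * (Q1 - 1) / 2
}

#' Expected richness in a subsample of t sampling units
#'
#' Expected number of taxa detected in `t` of the `T` units drawn without
#' replacement: S_obs - sum_i C(T - Y_i, t) / C(T, t). Binomial
#' coefficients are evaluated on the log scale for stability.
#'
#' @param data an `incidence_data`.
#' @param t number of units, 1 <= t <= T.
#' @return expected richness (vectorised over `t`).
#' @export
interpolate_richness <- function(data, t) {
  stopifnot(inherits(data, "incidence_data"))
  if (any(t < 1 | t > data$T)) stop("t must lie in [1, T]")
  vapply(t, function(tt) {
    lo <- data$T - data$Y          # units without taxon i
    p_absent <- ifelse(lo >= tt,
                       exp(lchoose(lo, tt) - lchoose(data$T, tt)),
                       0)
    data$S_obs - sum(p_absent)
  }, numeric(1))
}

#' Expected richness extrapolated t_star units beyond T
#'
#' S_obs + Q0_hat (1 - (1 - Q1 / (Q1 + T Q0_hat))^t_star), where Q0_hat is
#' the Chao2 estimate of undetected richness. With no singletons the curve
#' stays flat at S_obs.
#'
#' @param data an `incidence_data`.
#' @param t_star number of additional units (vectorised, >= 0).
#' @return expected richness at effort T + t_star.
#' @export
extrapolate_richness <- function(data, t_star) {
  stopifnot(inherits(data, "incidence_data"), all(t_star >= 0))
  Q0 <- chao2(data) - data$S_obs
  Q1 <- sum(data$Y == 1)
  if (Q0 <= 0 || Q1 == 0) return(rep(data$S_obs, length(t_star)))
  data$S_obs + Q0 * (1 - (1 - Q1 / (Q1 + data$T * Q0))^t_star)
}

#' Rarefaction/extrapolation curve
#'
#' Evaluates expected richness on a grid of efforts from 1 to `endpoint`
#' (default 2T, the doubling convention), always including the observed
#' effort T. Points below T are interpolated, T is observed, points above
#' are extrapolated; the curve is continuous at T.
#'
#' @param data an `incidence_data`.
#' @param n_knots number of grid knots (default 40).
#' @param endpoint largest effort (default `2 * data$T`).
#' @return object of class `rarefaction_curve`: data.frame with columns
#'   `t`, `estimate`, `kind`, plus attributes `asymptote` (Chao2), `entity`,
#'   `habitat`.
#' @export
build_curve <- function(data, n_knots = 40L, endpoint = NULL) {
  stopifnot(inherits(data, "incidence_data"))
  if (is.null(endpoint)) endpoint <- 2L * data$T
  grid <- sort(unique(c(round(seq(1, endpoint, length.out = n_knots)),
                        data$T)))
  grid <- grid[grid >= 1]
  est <- numeric(length(grid))
  kind <- character(length(grid))
  for (i in seq_along(grid)) {
    tt <- grid[i]
    if (tt < data$T) {
      est[i] <- interpolate_richness(data, tt)
      kind[i] <- "interpolated"
    } else if (tt == data$T) {
      est[i] <- data$S_obs
      kind[i] <- "observed"
    } else {
      est[i] <- extrapolate_richness(data, tt - data$T)
      kind[i] <- "extrapolated"
    }
  }
  structure(data.frame(t = grid, estimate = est, kind = kind,
                       stringsAsFactors = FALSE),
            asymptote = chao2(data), entity = data$entity,
            habitat = data$habitat, class = c("rarefaction_curve",
                                              "data.frame"))
}

#' Rarefaction curves for all habitats and entity classes
#'
#' @param networks a `network_set`.
#' @param entities entity classes to cover.
#' @param n_knots grid knots per curve.
#' @return data.frame with columns habitat, entity, t, estimate, kind,
#'   chao2_asymptote.
#' @export
rarefaction_table <- function(networks,
                              entities = c("host", "diptera", "interaction"),
                              n_knots = 40L) {
  out <- list()
  for (ent in entities) {
    inc <- incidence_from_networks(networks, ent)
    for (h in names(inc)) {
      cv <- build_curve(inc[[h]], n_knots = n_knots)
      out[[length(out) + 1L]] <-
        data.frame(habitat = h, entity = ent, t = cv$t,
                   estimate = cv$estimate, kind = cv$kind,
                   chao2_asymptote = attr(cv, "asymptote"),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
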