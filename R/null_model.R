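#' @title Domestic-host removal null model
#' @name null_model
#' @description
#' Tests whether humans and their domesticated animals structure a network's
#' interaction evenness: the k domestic host columns present in a network
#' are removed (targeted removal) and the resulting IE is compared, via a
#' z-score, against the distribution of IE values obtained by removing k
#' randomly chosen host species (domestic or not), replicated `n_reps`
#' times.
NULL

#' Default domestic-host list
#'
#' Humans plus the eight domesticated animals of the targeted-removal model
#' (chickens, dogs, cats, goats, cattle, horses, pigs, sheep). Matching
#' against host node labels is case-insensitive and goes through a synonym
#' map so that e.g. "Bos taurus" and "Cattle" hit the same entry.
#'
#' @return list with elements `hosts` (canonical names) and `synonyms`
#'   (named character vector, label -> canonical name).
#' @export
default_domestic_hosts <- function() {
  list(
    hosts = c("human", "chicken", "dog", "cat", "goat", "cattle", "horse",
              "pig", "sheep"),
    synonyms = c(
      "homo sapiens" = "human",
      "gallus gallus" = "chicken",
      "gallus gallus domesticus" = "chicken",
      "canis familiaris" = "dog",
      "canis lupus familiaris" = "dog",
      "felis catus" = "cat",
      "capra hircus" = "goat",
      "bos taurus" = "cattle",
      "bos indicus" = "cattle",
      "cow" = "cattle",
      "bovine" = "cattle",
      "equus caballus" = "horse",
      "equus ferus caballus" = "horse",
      "sus scrofa domesticus" = "pig",
      "sus domesticus" = "pig",
      "ovis aries" = "sheep"))
}

#' Read a domestic-host list from file
#'
#' One host name per line; an optional second comma-separated column gives
#' the canonical name a synonym maps to.
#'
#' @param path text file path.
#' @return a domestic-host list as in [default_domestic_hosts()].
#' @export
read_domestic_hosts <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines[nzchar(trimws(lines))])
  parts <- strsplit(lines, ",")
  hosts <- character()
  synonyms <- character()
  for (p in parts) {
    p <- trimws(p)
    if (length(p) == 1L) hosts <- c(hosts, tolower(p))
    else synonyms[tolower(p[1])] <- tolower(p[2])
  }
  hosts <- unique(c(hosts, unname(synonyms)))
  if (length(hosts) == 0) stop("domestic-host list is empty")
  list(hosts = hosts, synonyms = synonyms)
}

#' Which host labels are domestic?
#'
#' @param labels host node labels.
#' @param domestic a domestic-host list.
#' @return logical vector along `labels`.
#' @export
is_domestic <- function(labels, domestic = default_domestic_hosts()) {
  low <- tolower(labels)
  low %in% domestic$hosts | low %in% names(domestic$synonyms)
}

#' Remove named host columns from a network
#'
#' Deletes the named columns, then any Diptera row whose total drops to
#' zero. Host names not present are ignored with a warning. If the removal
#' empties the matrix the result carries attribute `empty = TRUE` instead of
#' erroring.
#'
#' @param matrix an `interaction_matrix`.
#' @param hosts host labels to delete.
#' @return the reduced `interaction_matrix`.
#' @export
remove_hosts <- function(matrix, hosts) {
  labels <- colnames(matrix$weights)
  missing <- setdiff(hosts, labels)
  if (length(missing) > 0)
    warning("host label(s) not present, ignored: ",
            paste(sQuote(missing), collapse = ", "))
  keep <- !(labels %in% hosts)
  matrix$weights <- matrix$weights[, keep, drop = FALSE]
  drop_empty(matrix)
}

.ie_or_na <- function(matrix, ie_mode) {
  if (isTRUE(attr(matrix, "empty"))) return(NA_real_)
  tryCatch(interaction_evenness(matrix, ie_mode), error = function(e) NA_real_)
}

#' Run the targeted-removal null model on one network
#'
#' Removes all domestic host columns (targeted) and compares the resulting
#' IE against `n_reps` random removals of the same number of host columns,
#' drawn uniformly without replacement from all hosts. Replicates whose IE
#' is undefined (fewer than two links left) are redrawn, up to `10 * n_reps`
#' redraws in total. Networks that cannot support the comparison are
#' returned with `skipped = TRUE` and a reason: no domestic host present,
#' every host domestic (random = targeted), undefined targeted IE, or
#' redraw exhaustion.
#'
#' z = (ie_targeted - mean(ie_random)) / sd(ie_random); when sd = 0 the
#' z-score is 0 if the targeted value equals the degenerate distribution and
#' flagged undefined otherwise.
#'
#' @param matrix an `interaction_matrix`.
#' @param domestic domestic-host list.
#' @param n_reps number of random-removal replicates (default 100).
#' @param seed integer seed; the whole result is reproducible from it.
#' @param ie_mode IE denominator mode.
#' @return object of class `null_model_result`: list with `network_id`,
#'   `habitat`, `k_removed`, `ie_observed`, `ie_targeted`, `ie_random`
#'   (length `n_reps`), `z`, `n_redraws`, `seed`, `skipped`, `reason`.
#' @export
run_null_model <- function(matrix, domestic = default_domestic_hosts(),
                           n_reps = 100L, seed = 1L,
                           ie_mode = "realized_links") {
  labels <- colnames(matrix$weights)
  dom <- labels[is_domestic(labels, domestic)]
  k <- length(dom)
  base <- list(network_id = matrix$network_id, habitat = matrix$habitat,
               k_removed = k, ie_observed = .ie_or_na(matrix, ie_mode),
               ie_targeted = NA_real_, ie_random = numeric(0), z = NA_real_,
               n_redraws = 0L, seed = seed, skipped = TRUE, reason = "")

  skip <- function(reason) {
    base$reason <- reason
    structure(base, class = "null_model_result")
  }
  if (length(domestic$hosts) == 0) return(skip("empty domestic-host list"))
  if (k == 0L) return(skip("no domestic hosts in network"))
  if (k == length(labels))
    return(skip("all hosts domestic: random removal equals targeted"))

  ie_targeted <- .ie_or_na(remove_hosts(matrix, dom), ie_mode)
  if (is.na(ie_targeted))
    return(skip("IE undefined after targeted removal"))
  base$ie_targeted <- ie_targeted

  set.seed(seed)
  draws <- numeric(n_reps)
  redraws <- 0L
  for (b in seq_len(n_reps)) {
    repeat {
      pick <- sample(labels, k)
      ie <- .ie_or_na(suppressWarnings(remove_hosts(matrix, pick)), ie_mode)
      if (!is.na(ie)) break
      redraws <- redraws + 1L
      if (redraws > 10L * n_reps)
        return(skip("random replicates kept yielding undefined IE"))
    }
    draws[b] <- ie
  }
  base$ie_random <- draws
  base$n_redraws <- redraws
  base$skipped <- FALSE

  s <- stats::sd(draws)
  if (s > 0) {
    base$z <- (ie_targeted - mean(draws)) / s
  } else if (abs(ie_targeted - mean(draws)) < 1e-12) {
    base$z <- 0
  } else {
    base$z <- NA_real_
    base$reason <- "z undefined: zero variance among random removals"
  }
  structure(base, class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  if (x$skipped) {
    cat(sprintf("null_model_result %s: skipped (%s)\n", x$network_id, x$reason))
  } else {
    cat(sprintf(
      "null_model_result %s: k = %d, IE targeted = %.3f, z = %.3f\n",
      x$network_id, x$k_removed, x$ie_targeted, x$z))
  }
  invisible(x)
}

#' Run the null model across a network set
#'
#' @param networks a `network_set` or list of `interaction_matrix`.
#' @inheritParams run_null_model
#' @return list of `null_model_result`, one per network; each network gets
#'   its own seed derived as `seed + index` so results are reproducible and
#'   independent of evaluation order.
#' @export
run_null_models <- function(networks, domestic = default_domestic_hosts(),
                            n_reps = 100L, seed = 1L,
                            ie_mode = "realized_links") {
  nets <- if (inherits(networks, "network_set")) networks$networks
          else networks
  out <- vector("list", length(nets))
  for (i in seq_along(nets)) {
    out[[i]] <- run_null_model(nets[[i]], domestic, n_reps,
                               seed = seed + i, ie_mode = ie_mode)
  }
  names(out) <- vapply(out, `[[`, character(1), "network_id")
  out
}

#' Per-habitat summary of targeted-removal evenness
#'
#' Mean, n, and standard error (sd / sqrt(n)) of the targeted-removal IE
#' values of the non-skipped networks, by habitat.
#'
#' @param results list of `null_model_result`.
#' @return data.frame with columns habitat, mean_ie_targeted, n, se.
#' @export
summarise_null_by_habitat <- function(results) {
  ok <- Filter(function(r) !r$skipped, results)
  if (length(ok) == 0) stop("no non-skipped null-model results to summarise")
  df <- data.frame(
    habitat = vapply(ok, `[[`, character(1), "habitat"),
    ie_targeted = vapply(ok, `[[`, numeric(1), "ie_targeted"))
  habs <- unique(vapply(results, `[[`, character(1), "habitat"))
  missing <- setdiff(habs[!is.na(habs)], df$habitat)
  if (length(missing) > 0)
    warning("habitat(s) with all networks skipped omitted: ",
            paste(missing, collapse = ", "))
  out <- do.call(rbind, lapply(split(df, df$habitat), function(g) {
    n <- nrow(g)
    data.frame(habitat = g$habitat[1],
               mean_ie_targeted = mean(g$ie_targeted),
               n = n,
               se = if (n > 1) stats::sd(g$ie_targeted) / sqrt(n) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Tabulate null-model results for export
#'
#' @param results list of `null_model_result`.
#' @return data.frame, one row per network.
#' @export
null_model_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(network_id = r$network_id, habitat = r$habitat,
               k_removed = r$k_removed, ie_observed = r$ie_observed,
               ie_targeted = r$ie_targeted,
               ie_random_mean = if (length(r$ie_random)) mean(r$ie_random)
                                else NA_real_,
               z = r$z, n_reps = length(r$ie_random), seed = r$seed,
               skipped = r$skipped, reason = r$reason,
               stringsAsFactors = FALSE)
  }))
}
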