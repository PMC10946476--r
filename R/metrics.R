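#' @title Network-level metrics: interaction evenness and H2'
#' @name metrics
#' @description
#' Two weighted network metrics are computed from each interaction matrix.
#' Interaction evenness, IE = H / ln L, is the Shannon entropy H of the
#' link-weight proportions divided by the log of the number of links L: 1
#' when every link carries equal weight, low when a few species pairs
#' dominate. H2' standardises the observed two-dimensional entropy between
#' the minimum and maximum entropy achievable by any nonnegative integer
#' matrix with the same row and column totals: 0 at the random-expectation
#' extreme (maximal generalisation), 1 at maximal specialisation.
NULL

# sum x log x over positive cells (the unnormalised entropy kernel)
.xlogx <- function(n) {
  x <- n[n > 0]
  sum(x * log(x))
}

.entropy_counts <- function(n) {
  m <- sum(n)
  if (m <= 0) stop("entropy undefined for an all-zero matrix")
  log(m) - .xlogx(n) / m
}

#' Shannon entropy of interaction weights
#'
#' H = -sum p ln p over positive cells, with p the cell weight divided by
#' matrix size m. Natural logarithms; a single-link matrix has H = 0.
#'
#' @param matrix an `interaction_matrix` or plain numeric matrix.
#' @return entropy in nats.
#' @export
shannon_entropy <- function(matrix) {
  .entropy_counts(im_weights(matrix))
}

#' Interaction evenness
#'
#' IE = H / ln(L). The denominator is, by default, the number of realized
#' links (positive cells), matching the formula IE = H / ln L; the
#' alternative `all_cells` mode divides by the log of the number of matrix
#' cells (rows x columns), the convention of some network toolkits. The
#' metric is undefined when the denominator is ln 1 = 0.
#'
#' @param matrix an `interaction_matrix` or numeric matrix.
#' @param denominator_mode `"realized_links"` (default) or `"all_cells"`.
#' @return evenness in \[0, 1\].
#' @export
interaction_evenness <- function(matrix,
                                 denominator_mode = c("realized_links",
                                                      "all_cells")) {
  denominator_mode <- match.arg(denominator_mode)
  w <- im_weights(matrix)
  denom <- if (denominator_mode == "realized_links") sum(w > 0)
           else length(w)
  if (denom < 2)
    stop("interaction evenness undefined: ln(", denom, ") denominator")
  pos <- w[w > 0]
  # equal weights maximise evenness: return 1 without round-off
  if (denominator_mode == "realized_links" &&
      length(unique(pos)) == 1L) return(1)
  shannon_entropy(w) / log(denom)
}

# -- integer-feasible entropy extrema under fixed marginals ------------------

# Maximally even integer fill: start from the floor of the proportional
# expectation r_i * c_j / m, then hand out the remaining units to the most
# underfilled cells whose row and column still have a deficit.
.fill_even <- function(r, c) {
  m <- sum(r)
  E <- outer(r, c) / m
  n <- floor(E)
  dr <- r - rowSums(n)
  dc <- c - colSums(n)
  nr <- length(r)
  while (sum(dr) > 0) {
    ord <- order(E - n, decreasing = TRUE)
    progressed <- FALSE
    for (k in ord) {
      i <- (k - 1L) %% nr + 1L
      j <- (k - 1L) %/% nr + 1L
      if (dr[i] > 0 && dc[j] > 0) {
        n[k] <- n[k] + 1
        dr[i] <- dr[i] - 1
        dc[j] <- dc[j] - 1
        progressed <- TRUE
      }
    }
    if (!progressed) stop("internal error: infeasible even fill")
  }
  n
}

# Maximally specialised integer fill: repeatedly pair the largest remaining
# row total with the largest remaining column total. The "exact" variant
# prefers a row/column pair with identical remaining totals, which lets
# whole blocks close at once.
.fill_specialised <- function(r, c, tie = c("first", "last", "exact")) {
  tie <- match.arg(tie)
  pick_last <- function(x) length(x) + 1L - which.max(rev(x))
  n <- matrix(0, length(r), length(c))
  repeat {
    if (tie == "exact") {
      hit <- which(outer(r, c, function(a, b) a == b & a > 0),
                   arr.ind = TRUE)
      if (nrow(hit) > 0) {
        best <- which.max(r[hit[, 1]])
        i <- hit[best, 1]; j <- hit[best, 2]
      } else {
        i <- which.max(r); j <- which.max(c)
      }
    } else if (tie == "first") {
      i <- which.max(r); j <- which.max(c)
    } else {
      i <- pick_last(r); j <- pick_last(c)
    }
    if (r[i] == 0 || c[j] == 0) break
    a <- min(r[i], c[j])
    n[i, j] <- n[i, j] + a
    r[i] <- r[i] - a
    c[j] <- c[j] - a
  }
  n
}

# northwest-corner fill under given row/column orders: visits a vertex of
# the transportation polytope for every ordering
.fill_nw <- function(r, c, rperm, cperm) {
  n <- matrix(0, length(r), length(c))
  i <- 1L; j <- 1L
  while (i <= length(rperm) && j <= length(cperm)) {
    ri <- rperm[i]; cj <- cperm[j]
    a <- min(r[ri], c[cj])
    n[ri, cj] <- n[ri, cj] + a
    r[ri] <- r[ri] - a
    c[cj] <- c[cj] - a
    if (r[ri] == 0) i <- i + 1L
    if (c[cj] == 0) j <- j + 1L
  }
  n
}

.permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in .permutations(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Steepest 2x2 unit-swap search on sum(x log x) under fixed marginals.
# direction = +1 maximises sum x log x (minimises entropy), -1 the reverse.
.swap_optimize <- function(n, direction, max_moves = 2000L) {
  nr <- nrow(n); nc <- ncol(n)
  if (nr < 2 || nc < 2) return(n)
  gl <- function(x) ifelse(x > 0, x * log(x), 0)
  for (move in seq_len(max_moves)) {
    dinc <- gl(n + 1) - gl(n)
    ddec <- gl(pmax(n - 1, 0)) - gl(n)
    ddec[n == 0] <- if (direction > 0) -Inf else Inf
    best <- 1e-10
    best_move <- NULL
    for (i1 in seq_len(nr)) for (i2 in seq_len(nr)) {
      if (i1 == i2) next
      # move: n[i1,j1]+1, n[i1,j2]-1, n[i2,j1]-1, n[i2,j2]+1
      u <- dinc[i1, ] + ddec[i2, ]
      v <- ddec[i1, ] + dinc[i2, ]
      delta <- outer(u, v, "+") * direction
      diag(delta) <- -Inf
      k <- which.max(delta)
      if (delta[k] > best) {
        j1 <- (k - 1L) %% nc + 1L
        j2 <- (k - 1L) %/% nc + 1L
        best <- delta[k]
        best_move <- c(i1, i2, j1, j2)
      }
    }
    if (is.null(best_move)) break
    i1 <- best_move[1]; i2 <- best_move[2]
    j1 <- best_move[3]; j2 <- best_move[4]
    n[i1, j1] <- n[i1, j1] + 1
    n[i1, j2] <- n[i1, j2] - 1
    n[i2, j1] <- n[i2, j1] - 1
    n[i2, j2] <- n[i2, j2] + 1
  }
  n
}

#' Entropy extrema of integer matrices with fixed marginal totals
#'
#' Computes the minimum and maximum Shannon entropy over nonnegative integer
#' matrices sharing the observed row and column sums. The maximum uses a
#' proportional-fill heuristic with integer adjustment; the minimum a greedy
#' largest-remaining-marginal packing (two tie-break variants). Both are
#' refined by a steepest 2x2 unit-swap local search on matrices up to
#' `refine_cells` cells. The observed entropy is guaranteed to lie in
#' \[H2min, H2max\] by clamping; clamp events are flagged and signalled as a
#' warning because they mean the heuristic was beaten by the observed
#' arrangement.
#'
#' @param matrix an `interaction_matrix` or numeric integer matrix.
#' @param refine_cells apply the swap search when rows x cols is at most
#'   this (default 400).
#' @return list with `H2min`, `H2max` (nats), and logical flags
#'   `clamped_min`, `clamped_max`.
#' @export
h2_extrema <- function(matrix, refine_cells = 400L) {
  w <- im_weights(matrix)
  if (sum(w) <= 0) stop("entropy extrema undefined for an all-zero matrix")
  r <- rowSums(w)
  c <- colSums(w)
  refine <- length(w) <= refine_cells

  starts <- list(.fill_even(r, c),
                 .fill_specialised(r, c, tie = "first"),
                 .fill_specialised(r, c, tie = "last"),
                 .fill_specialised(r, c, tie = "exact"),
                 w)
  if (length(r) <= 4 && length(c) <= 4) {
    # small matrices: also seed the search from every northwest-corner
    # vertex of the transportation polytope
    rp <- .permutations(length(r))
    cp <- .permutations(length(c))
    for (a in rp) for (b in cp)
      starts[[length(starts) + 1L]] <- .fill_nw(r, c, a, b)
  }
  if (refine) {
    asc <- lapply(starts, .swap_optimize, direction = -1)
    nmax <- asc[[which.min(vapply(asc, .xlogx, numeric(1)))]]
    des <- lapply(starts, .swap_optimize, direction = +1)
    nmin <- des[[which.max(vapply(des, .xlogx, numeric(1)))]]
  } else {
    nmax <- starts[[1]]
    spec <- starts[2:4]
    nmin <- spec[[which.max(vapply(spec, .xlogx, numeric(1)))]]
  }

  H <- .entropy_counts(w)
  H2max <- .entropy_counts(nmax)
  H2min <- .entropy_counts(nmin)

  clamped_max <- H > H2max + 1e-12
  clamped_min <- H < H2min - 1e-12
  if (clamped_max) {
    warning("h2_extrema: observed entropy exceeded heuristic maximum; clamped")
    H2max <- H
  }
  if (clamped_min) {
    warning("h2_extrema: observed entropy below heuristic minimum; clamped")
    H2min <- H
  }
  list(H2min = H2min, H2max = H2max,
       clamped_min = clamped_min, clamped_max = clamped_max)
}

#' H2' network specialisation index
#'
#' H2' = (H2max - H2) / (H2max - H2min): 0 when the observed interaction
#' frequencies match the proportional (random) expectation, 1 when the
#' network is as specialised as its marginal totals allow. When the
#' marginals admit no entropy range (H2max = H2min, e.g. a 1 x n matrix)
#' the index is returned as 0 with attribute `degenerate = TRUE`.
#'
#' @param matrix an `interaction_matrix` or numeric integer matrix.
#' @param extrema optional precomputed result of [h2_extrema()].
#' @return H2' in \[0, 1\]; attributes `degenerate`, `clamped`.
#' @export
h2_prime <- function(matrix, extrema = NULL) {
  w <- im_weights(matrix)
  if (is.null(extrema)) extrema <- h2_extrema(w)
  rng <- extrema$H2max - extrema$H2min
  clamped <- isTRUE(extrema$clamped_min) || isTRUE(extrema$clamped_max)
  if (rng <= 1e-12) {
    return(structure(0, degenerate = TRUE, clamped = clamped))
  }
  H <- .entropy_counts(w)
  val <- (extrema$H2max - H) / rng
  structure(min(max(val, 0), 1), degenerate = FALSE, clamped = clamped)
}

#' Per-network metric summary
#'
#' Computes the full metric row for one network: interaction evenness, H2'
#' and its entropy extrema, species richness S (rows + columns), matrix size
#' m (sum of all interactions), realized links L, dominant Diptera family,
#' habitat and absolute latitude. Metric failures (e.g. IE undefined for a
#' single-link network) are recorded in a `flags` field rather than raised,
#' so batch runs over many networks complete.
#'
#' @param matrix an `interaction_matrix`.
#' @param ie_mode denominator mode passed to [interaction_evenness()].
#' @param h2 compute H2' and its extrema (default TRUE); skipping them makes
#'   large simulation batches cheaper when only IE is analysed.
#' @return one-row data.frame (fields described above).
#' @export
network_summary <- function(matrix, ie_mode = "realized_links", h2 = TRUE) {
  w <- matrix$weights
  m <- sum(w)
  L <- sum(w > 0)
  flags <- character()

  ie <- tryCatch(interaction_evenness(matrix, ie_mode), error = function(e) {
    flags <<- c(flags, "ie_undefined")
    NA_real_
  })
  H <- shannon_entropy(w)

  if (h2) {
    ext <- withCallingHandlers(
      h2_extrema(w),
      warning = function(wrn) invokeRestart("muffleWarning"))
    h2p <- h2_prime(w, ext)
    if (isTRUE(attr(h2p, "degenerate"))) flags <- c(flags, "h2_degenerate")
    if (isTRUE(attr(h2p, "clamped"))) flags <- c(flags, "h2_clamped")
    h2min <- ext$H2min; h2max <- ext$H2max; h2p <- as.numeric(h2p)
  } else {
    h2min <- h2max <- h2p <- NA_real_
  }

  fam <- dominant_family(matrix)
  data.frame(
    network_id = matrix$network_id,
    study_id = matrix$study_id,
    habitat = matrix$habitat,
    latitude = matrix$latitude,
    abs_latitude = abs(matrix$latitude),
    dominant_family = as.character(fam),
    n_diptera = nrow(w),
    n_hosts = ncol(w),
    S = nrow(w) + ncol(w),
    m = m,
    L = L,
    IE = ie,
    ie_mode = ie_mode,
    H2 = H,
    H2min = h2min,
    H2max = h2max,
    H2prime = h2p,
    flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Metric summaries for every network in a set
#'
#' @param networks a `network_set`.
#' @inheritParams network_summary
#' @return data.frame with one row per network.
#' @export
summarise_networks <- function(networks, ie_mode = "realized_links",
                               h2 = TRUE) {
  nets <- if (inherits(networks, "network_set")) networks$networks
          else networks
  do.call(rbind, lapply(nets, network_summary, ie_mode = ie_mode, h2 = h2))
}
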