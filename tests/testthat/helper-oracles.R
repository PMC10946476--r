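# Independent oracles and fixture builders. These deliberately avoid the
# package's own algorithms: extrema by exhaustive enumeration, rarefaction
# by exhaustive subset enumeration, entropy by direct evaluation.

entropy_of_counts <- function(n) {
  p <- n[n > 0] / sum(n)
  -sum(p * log(p))
}

# all nonnegative integer matrices with the given row/column sums,
# enumerated row by row
enumerate_marginal_matrices <- function(r, c) {
  out <- list()
  compositions <- function(total, caps) {
    # all vectors x >= 0, sum x = total, x[i] <= caps[i]
    if (length(caps) == 1L) {
      if (total <= caps[1]) return(list(total)) else return(list())
    }
    res <- list()
    for (v in 0:min(total, caps[1])) {
      for (rest in compositions(total - v, caps[-1])) {
        res[[length(res) + 1L]] <- c(v, rest)
      }
    }
    res
  }
  recurse <- function(rows_left, col_rem, acc) {
    if (length(rows_left) == 0L) {
      if (all(col_rem == 0)) out[[length(out) + 1L]] <<- do.call(rbind, acc)
      return(invisible())
    }
    for (row in compositions(rows_left[1], col_rem)) {
      recurse(rows_left[-1], col_rem - row, c(acc, list(row)))
    }
  }
  recurse(r, c, list())
  out
}

# exact entropy extrema over the transportation polytope (tiny cases only)
oracle_extrema <- function(w) {
  mats <- enumerate_marginal_matrices(rowSums(w), colSums(w))
  ents <- vapply(mats, entropy_of_counts, numeric(1))
  list(H2min = min(ents), H2max = max(ents), n_matrices = length(mats))
}

# expected richness in t of T units by full subset enumeration (T <= 10)
oracle_interpolate <- function(Y, T, t) {
  # unit u contains taxon i iff u <= Y_i under an arbitrary fixed layout;
  # expectation over subsets depends only on the Y_i, so any layout works
  subsets <- utils::combn(T, t)
  mean(apply(subsets, 2, function(u) sum(vapply(Y, function(y)
    any(u <= y), logical(1)))))
}

# random small integer matrix with no empty rows/columns
random_small_matrix <- function(max_dim = 3L, max_total = 12L) {
  repeat {
    nr <- sample(2:max_dim, 1)
    nc <- sample(2:max_dim, 1)
    m <- sample(max(nr, nc):max_total, 1)
    w <- matrix(0L, nr, nc)
    idx <- cbind(sample(nr, m, replace = TRUE), sample(nc, m, replace = TRUE))
    for (k in seq_len(m)) w[idx[k, 1], idx[k, 2]] <- w[idx[k, 1], idx[k, 2]] + 1L
    if (all(rowSums(w) > 0) && all(colSums(w) > 0)) return(w)
  }
}

# minimal well-formed record table
make_records <- function(study = "S01", habitat = "NearNatural",
                         latitude = 10, diptera = c("Culex pipiens",
                                                    "Aedes vexans"),
                         hosts = c("Human", "Turdus merula"),
                         counts = NULL) {
  grid <- expand.grid(diptera_taxon = diptera, host_taxon = hosts,
                      stringsAsFactors = FALSE)
  if (is.null(counts)) counts <- seq_len(nrow(grid))
  data.frame(study_id = study, site_id = study, latitude = latitude,
             habitat = habitat, diptera_taxon = grid$diptera_taxon,
             diptera_rank = "species", diptera_family = "Culicidae",
             host_taxon = grid$host_taxon, host_rank = "species",
             count = as.integer(counts), stringsAsFactors = FALSE)
}

write_temp_records <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}
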