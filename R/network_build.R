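#' @title Weighted bipartite network construction
#' @name network_build
#' @description
#' Each study-by-habitat combination yields one weighted antagonistic
#' bipartite network: a Diptera (rows) by vertebrate host (columns) matrix
#' of blood-meal counts. Studies that contribute only a single Diptera
#' species do not constitute network data and are excluded.
NULL

#' Construct an interaction matrix object
#'
#' Low-level constructor used by [build_matrix()] and in tests. Rows are
#' Diptera, columns are hosts, cells are blood-meal counts.
#'
#' @param weights nonnegative integer matrix with dimnames.
#' @param row_family character vector of Diptera families, one per row
#'   (recycled if length 1).
#' @param study_id,habitat,latitude network metadata.
#' @return an object of class `interaction_matrix`.
#' @export
interaction_matrix <- function(weights, row_family = "Other",
                               study_id = "study", habitat = NA_character_,
                               latitude = NA_real_) {
  weights <- as.matrix(weights)
  if (is.null(rownames(weights)))
    rownames(weights) <- sprintf("D%02d", seq_len(nrow(weights)))
  if (is.null(colnames(weights)))
    colnames(weights) <- sprintf("H%02d", seq_len(ncol(weights)))
  if (any(weights < 0) || any(weights != round(weights)))
    stop("interaction weights must be nonnegative integers")
  row_family <- rep_len(row_family, nrow(weights))
  names(row_family) <- rownames(weights)
  structure(list(weights = weights, row_family = row_family,
                 network_id = paste(study_id, habitat, sep = "::"),
                 study_id = study_id, habitat = habitat, latitude = latitude),
            class = "interaction_matrix")
}

im_weights <- function(x) {
  if (inherits(x, "interaction_matrix")) x$weights else as.matrix(x)
}

#' @export
print.interaction_matrix <- function(x, ...) {
  w <- x$weights
  cat(sprintf("interaction_matrix %s: %d Diptera x %d hosts, m = %d, L = %d\n",
              x$network_id, nrow(w), ncol(w), sum(w), sum(w > 0)))
  invisible(x)
}

#' Drop empty rows and columns from an interaction matrix
#'
#' @param matrix an `interaction_matrix`.
#' @return the matrix without all-zero rows/columns; if everything is empty
#'   the returned object carries attribute `empty = TRUE`.
#' @export
drop_empty <- function(matrix) {
  w <- matrix$weights
  keep_r <- rowSums(w) > 0
  keep_c <- colSums(w) > 0
  w <- w[keep_r, keep_c, drop = FALSE]
  matrix$weights <- w
  matrix$row_family <- matrix$row_family[keep_r]
  if (nrow(w) == 0 || ncol(w) == 0) attr(matrix, "empty") <- TRUE
  matrix
}

#' Build the interaction matrix of one network
#'
#' All rows must share one (study_id, habitat) pair. Cell (i, j) is the
#' summed blood-meal count of (Diptera i, host j); rows and columns are
#' sorted lexicographically so the matrix is invariant to input row order.
#'
#' @param records subset of a record table from one study and habitat.
#' @return an `interaction_matrix`.
#' @export
build_matrix <- function(records) {
  stopifnot(nrow(records) > 0)
  if (length(unique(records$study_id)) != 1L ||
      length(unique(records$habitat)) != 1L)
    stop("build_matrix needs rows from a single (study_id, habitat)")
  lats <- unique(records$latitude)
  if (length(lats) > 1L)
    stop("conflicting latitude values within one network: ",
         paste(lats, collapse = ", "))

  dl <- sort(unique(records$diptera_taxon), method = "radix")
  hl <- sort(unique(records$host_taxon), method = "radix")
  w <- matrix(0L, length(dl), length(hl), dimnames = list(dl, hl))
  i <- match(records$diptera_taxon, dl)
  j <- match(records$host_taxon, hl)
  for (k in seq_len(nrow(records)))
    w[i[k], j[k]] <- w[i[k], j[k]] + records$count[k]

  fam <- vapply(dl, function(d) {
    rows <- records$diptera_taxon == d
    tot <- tapply(records$count[rows], records$diptera_family[rows], sum)
    if (length(tot) > 1L)
      warning("Diptera taxon ", sQuote(d), " annotated with several families; ",
              "using the one with most meals")
    names(tot)[which.max(tot)]
  }, character(1))

  m <- interaction_matrix(w, row_family = fam,
                          study_id = records$study_id[1],
                          habitat = records$habitat[1], latitude = lats)
  drop_empty(m)
}

#' Split records into per-(study, habitat) networks
#'
#' Where a study sampled several habitat types, a separate network is built
#' for each habitat. Networks with fewer than `min_diptera` Diptera nodes
#' (default 2: single-species studies are not networks) are excluded and
#' listed in the result.
#'
#' @param records resolved record table.
#' @param min_diptera minimum number of Diptera rows for a network to count.
#' @return an object of class `network_set`: list with `networks` (named list
#'   of `interaction_matrix`), `exclusions` (data.frame), `provenance`.
#' @export
split_networks <- function(records, min_diptera = 2L) {
  if (nrow(records) == 0) {
    warning("empty record set: empty network set returned")
    return(structure(list(networks = list(),
                          exclusions = .empty_exclusions(),
                          provenance = list(n_records = 0L, total_count = 0L)),
                     class = "network_set"))
  }
  keys <- unique(records[, c("study_id", "habitat")])
  keys <- keys[order(keys$study_id, keys$habitat), , drop = FALSE]
  networks <- list()
  excl <- list()
  for (k in seq_len(nrow(keys))) {
    sub <- records[records$study_id == keys$study_id[k] &
                     records$habitat == keys$habitat[k], , drop = FALSE]
    mat <- build_matrix(sub)
    if (nrow(mat$weights) < min_diptera) {
      excl[[length(excl) + 1L]] <-
        data.frame(network_id = mat$network_id,
                   n_diptera = nrow(mat$weights),
                   reason = sprintf("fewer than %d Diptera nodes", min_diptera))
    } else {
      networks[[mat$network_id]] <- mat
    }
  }
  structure(list(
    networks = networks,
    exclusions = if (length(excl)) do.call(rbind, excl) else .empty_exclusions(),
    provenance = list(n_records = nrow(records),
                      total_count = sum(records$count))),
    class = "network_set")
}

.empty_exclusions <- function() {
  data.frame(network_id = character(), n_diptera = integer(),
             reason = character())
}

#' @export
print.network_set <- function(x, ...) {
  cat(sprintf("network_set: %d networks (%d excluded), %d records, %d meals\n",
              length(x$networks), nrow(x$exclusions),
              x$provenance$n_records, x$provenance$total_count))
  invisible(x)
}

#' Dominant Diptera family of a network
#'
#' The family whose rows carry the highest total interaction count. Exact
#' ties are broken alphabetically and flagged with attribute `tie = TRUE`.
#'
#' @param matrix an `interaction_matrix` with family annotation.
#' @return family name (character scalar), possibly with a `tie` attribute.
#' @export
dominant_family <- function(matrix) {
  fam <- matrix$row_family
  if (is.null(fam) || anyNA(fam))
    stop("missing family annotation on interaction matrix rows")
  tot <- tapply(rowSums(matrix$weights), fam, sum)
  top <- max(tot)
  winners <- sort(names(tot)[tot == top], method = "radix")
  out <- winners[1]
  if (length(winners) > 1L) attr(out, "tie") <- TRUE
  out
}

#' Aggregate a network set into one global network
#'
#' Union of all node labels; each cell is the summed weight of that
#' Diptera-host pair across networks.
#'
#' @param networks a `network_set` or list of `interaction_matrix`.
#' @return an `interaction_matrix` with `study_id = "aggregate"`.
#' @export
aggregate_global <- function(networks) {
  nets <- if (inherits(networks, "network_set")) networks$networks
          else networks
  if (length(nets) == 0) stop("cannot aggregate an empty network set")
  dl <- sort(unique(unlist(lapply(nets, function(n) rownames(n$weights)))),
             method = "radix")
  hl <- sort(unique(unlist(lapply(nets, function(n) colnames(n$weights)))),
             method = "radix")
  w <- matrix(0L, length(dl), length(hl), dimnames = list(dl, hl))
  fam_meals <- list()
  for (n in nets) {
    w[rownames(n$weights), colnames(n$weights)] <-
      w[rownames(n$weights), colnames(n$weights)] + n$weights
    for (r in rownames(n$weights)) {
      f <- n$row_family[[r]]
      fam_meals[[r]] <- c(fam_meals[[r]],
                          stats::setNames(sum(n$weights[r, ]), f))
    }
  }
  fam <- vapply(dl, function(d) {
    v <- fam_meals[[d]]
    tot <- tapply(v, names(v), sum)
    names(tot)[which.max(tot)]
  }, character(1))
  interaction_matrix(w, row_family = fam, study_id = "aggregate",
                     habitat = NA_character_, latitude = NA_real_)
}

#' Export a network as an edge list
#'
#' @param matrix an `interaction_matrix`.
#' @param path optional CSV output path; when `NULL` the edge list is
#'   returned only.
#' @return data.frame with columns diptera, host, weight (positive cells).
#' @export
edge_list <- function(matrix, path = NULL) {
  w <- matrix$weights
  idx <- which(w > 0, arr.ind = TRUE)
  el <- data.frame(diptera = rownames(w)[idx[, 1]],
                   host = colnames(w)[idx[, 2]],
                   weight = w[idx])
  el <- el[order(el$diptera, el$host), , drop = FALSE]
  rownames(el) <- NULL
  if (!is.null(path)) utils::write.csv(el, path, row.names = FALSE)
  el
}
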