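#' @title Blood-meal record input, validation and taxonomic resolution
#' @name records_io
#' @description
#' Blood-meal interaction records are the raw input of the pipeline: one row
#' per (study, site, habitat, Diptera taxon, host taxon) with the number of
#' identified blood meals. Records are read from CSV, validated against the
#' canonical schema, and taxonomically resolved: taxa not identified to
#' species level are either collapsed to a genus/family node or removed when
#' several unresolved species could be hiding in the same node.
NULL

#' Canonical habitat categories of anthropogenic landscape modification
#' @export
HABITAT_LEVELS <- c("Agricultural", "NearNatural", "VillageUrban")

#' Recognised biting-Diptera families
#' @export
DIPTERA_FAMILIES <- c("Culicidae", "Ceratopogonidae", "Glossinidae",
                      "Psychodidae", "Simuliidae", "Other")

.RECORD_COLS <- c("study_id", "site_id", "latitude", "habitat",
                  "diptera_taxon", "diptera_rank", "diptera_family",
                  "host_taxon", "host_rank", "count")

# ranks accepted on input; anything above family is dropped by resolve_taxa()
.RANKS <- c("species", "genus", "family", "order", "class", "phylum")

#' Read and validate a blood-meal record table
#'
#' Reads a CSV file with columns `study_id, site_id, latitude, habitat,
#' diptera_taxon, diptera_rank, diptera_family, host_taxon, host_rank, count`
#' and validates it: habitats must be one of [HABITAT_LEVELS], latitudes must
#' parse and lie in \[-90, 90\], counts must be nonnegative integers.
#' Rows with `count = 0` are dropped with a warning, and duplicate rows
#' (identical in everything but `count`) are summed with a warning.
#'
#' @param path path to a CSV file with a header row.
#' @param dialect field delimiter, default comma.
#' @return a validated `data.frame` of records (UTF-8 labels preserved).
#' @export
read_records <- function(path, dialect = ",") {
  if (!file.exists(path)) stop("record file not found: ", path)
  df <- utils::read.csv(path, sep = dialect, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", colClasses = "character",
                        check.names = FALSE)
  missing <- setdiff(.RECORD_COLS, names(df))
  if (length(missing) > 0) {
    stop("record schema error: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[, .RECORD_COLS]
  if (nrow(df) == 0) return(.finalise_records(df))

  # habitat enum
  bad_hab <- setdiff(unique(df$habitat), HABITAT_LEVELS)
  if (length(bad_hab) > 0) {
    stop("record schema error: unknown habitat label(s): ",
         paste(sQuote(bad_hab), collapse = ", "),
         "; allowed: ", paste(HABITAT_LEVELS, collapse = ", "))
  }
  bad_fam <- setdiff(unique(df$diptera_family), DIPTERA_FAMILIES)
  if (length(bad_fam) > 0) {
    stop("record schema error: unknown diptera_family label(s): ",
         paste(sQuote(bad_fam), collapse = ", "))
  }
  bad_rank <- setdiff(unique(c(df$diptera_rank, df$host_rank)), .RANKS)
  if (length(bad_rank) > 0) {
    stop("record schema error: unknown rank label(s): ",
         paste(sQuote(bad_rank), collapse = ", "))
  }

  lat <- suppressWarnings(as.numeric(df$latitude))
  bad <- which(is.na(lat))
  if (length(bad) > 0) {
    stop("record row error: unparseable latitude in row(s) ",
         paste(bad, collapse = ", "))
  }
  out_of_range <- which(lat < -90 | lat > 90)
  if (length(out_of_range) > 0) {
    stop("record row error: latitude outside [-90, 90] in row(s) ",
         paste(out_of_range, collapse = ", "))
  }

  cnt_ok <- grepl("^[0-9]+$", df$count)
  if (any(!cnt_ok)) {
    stop("record row error: count is not a nonnegative integer in row(s) ",
         paste(which(!cnt_ok), collapse = ", "),
         " (values: ", paste(sQuote(df$count[!cnt_ok]), collapse = ", "), ")")
  }
  df$latitude <- lat
  df$count <- as.integer(df$count)

  zero <- df$count == 0
  if (any(zero)) {
    warning(sum(zero), " row(s) with count = 0 dropped")
    df <- df[!zero, , drop = FALSE]
  }

  # sum duplicates of the full key
  key <- do.call(paste, c(df[setdiff(.RECORD_COLS, "count")], sep = "\r"))
  if (anyDuplicated(key)) {
    warning("duplicate record rows summed on read")
    cnt <- tapply(df$count, key, sum)
    df <- df[!duplicated(key), , drop = FALSE]
    df$count <- as.integer(cnt[key[!duplicated(key)]])
  }
  .finalise_records(df)
}

.finalise_records <- function(df) {
  rownames(df) <- NULL
  df
}

#' Write a blood-meal record table to CSV
#'
#' Inverse of [read_records()]: `read_records(write_records(x)) == x`.
#' Latitudes are written with enough digits for exact double round-trip.
#'
#' @param records a validated record table.
#' @param path output path.
#' @export
write_records <- function(records, path) {
  stopifnot(all(.RECORD_COLS %in% names(records)))
  out <- records[, .RECORD_COLS, drop = FALSE]
  out$latitude <- vapply(out$latitude, function(x)
    formatC(x, digits = 17, format = "g"), character(1))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Read a sympatry lookup table
#'
#' CSV with columns `taxon, study_id, n_sympatric_species`: for a genus (or
#' family) label at a given study location, the number of plausible sympatric
#' congeneric (confamilial) species.
#'
#' @param path path to CSV.
#' @return data.frame with the three columns.
#' @export
read_sympatry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("taxon", "study_id", "n_sympatric_species")
  if (!all(need %in% names(df))) {
    stop("sympatry schema error: need columns ", paste(need, collapse = ", "))
  }
  df$n_sympatric_species <- as.integer(df$n_sympatric_species)
  if (any(df$n_sympatric_species < 1, na.rm = TRUE)) {
    stop("sympatry table: n_sympatric_species must be >= 1")
  }
  df
}

# first whitespace-delimited token of a taxon label, e.g. the genus of
# "Culicoides sp. A" or of "Culicoides spp."
.label_head <- function(label) sub("\\s.*$", "", label)

.sympatry_lookup <- function(sympatry, taxon, study_id) {
  if (is.null(sympatry) || nrow(sympatry) == 0) return(NA_integer_)
  hit <- sympatry$taxon == taxon & sympatry$study_id == study_id
  if (!any(hit)) return(NA_integer_)
  max(sympatry$n_sympatric_species[hit])
}

#' Resolve taxon labels and apply exclusion rules
#'
#' Applies the node-labelling and exclusion rules to one side of the records
#' at a time (Diptera, then hosts):
#'
#' * rank above family: rows removed;
#' * a single unresolved taxon in a genus (or family) within a study: the
#'   node is labelled `"<Genus> spp."` and retained;
#' * multiple unresolved taxa sharing a genus (or family) within a study:
#'   retained (collapsed to one `"<Genus> spp."` node) only when the
#'   sympatry table reports no co-occurring congeners/confamilials
#'   (`n_sympatric_species == 1`); otherwise, or when the genus is absent
#'   from the sympatry table, all such rows are removed and the disposition
#'   is logged — never silently kept.
#'
#' Ambiguity grouping is per `study_id` (sympatry is a property of the
#' study location). After relabelling, rows that became identical are merged
#' by summing counts.
#'
#' @param records validated record table.
#' @param sympatry optional sympatry table from [read_sympatry()].
#' @return list with elements `records` (resolved table) and `log`, a
#'   resolution log with counts of removed hosts/Diptera/interactions, the
#'   label collapses, merged-row count, and per-decision dispositions.
#' @export
resolve_taxa <- function(records, sympatry = NULL) {
  df <- records
  n_in <- nrow(df)
  dispositions <- list()
  collapsed <- list()
  keep <- rep(TRUE, nrow(df))

  for (side in c("diptera", "host")) {
    taxon_col <- paste0(side, "_taxon")
    rank_col <- paste0(side, "_rank")

    above <- keep & df[[rank_col]] %in% c("order", "class", "phylum")
    if (any(above)) {
      for (tx in unique(df[[taxon_col]][above])) {
        dispositions[[length(dispositions) + 1L]] <-
          data.frame(side = side, taxon = tx, study_id = NA_character_,
                     action = "removed", reason = "rank above family")
      }
      keep[above] <- FALSE
    }

    unres <- keep & df[[rank_col]] %in% c("genus", "family")
    if (!any(unres)) next
    grp_head <- .label_head(df[[taxon_col]])
    groups <- unique(data.frame(study_id = df$study_id[unres],
                                head = grp_head[unres],
                                stringsAsFactors = FALSE))
    for (g in seq_len(nrow(groups))) {
      sid <- groups$study_id[g]
      head <- groups$head[g]
      sel <- unres & df$study_id == sid & grp_head == head
      labels <- unique(df[[taxon_col]][sel])
      node <- paste(head, "spp.")
      if (length(labels) == 1L) {
        # rule (a): single unresolved taxon -> genus/family node
        if (labels != node) {
          collapsed[[length(collapsed) + 1L]] <-
            data.frame(original = labels, node = node)
        }
        df[[taxon_col]][sel] <- node
      } else {
        n_sym <- .sympatry_lookup(sympatry, head, sid)
        if (!is.na(n_sym) && n_sym <= 1L) {
          # rule (b), no sympatric congeners: collapse into one node
          for (lab in setdiff(labels, node)) {
            collapsed[[length(collapsed) + 1L]] <-
              data.frame(original = lab, node = node)
          }
          df[[taxon_col]][sel] <- node
          dispositions[[length(dispositions) + 1L]] <-
            data.frame(side = side, taxon = head, study_id = sid,
                       action = "collapsed", reason = "no sympatric congeners")
        } else {
          reason <- if (is.na(n_sym)) {
            "unresolvable: genus absent from sympatry table"
          } else {
            sprintf("ambiguous: %d sympatric species possible", n_sym)
          }
          dispositions[[length(dispositions) + 1L]] <-
            data.frame(side = side, taxon = head, study_id = sid,
                       action = "removed", reason = reason)
          keep[sel] <- FALSE
        }
      }
    }
  }

  removed <- df[!keep, , drop = FALSE]
  df <- df[keep, , drop = FALSE]

  # merge rows that collapsed onto the same node
  n_before_merge <- nrow(df)
  if (nrow(df) > 0) {
    key <- do.call(paste, c(df[setdiff(.RECORD_COLS, "count")], sep = "\r"))
    if (anyDuplicated(key)) {
      cnt <- tapply(df$count, key, sum)
      df <- df[!duplicated(key), , drop = FALSE]
      df$count <- as.integer(cnt[key[!duplicated(key)]])
    }
  }
  rownames(df) <- NULL

  log <- list(
    removed_hosts = length(setdiff(unique(removed$host_taxon),
                                   unique(df$host_taxon))),
    removed_diptera = length(setdiff(unique(removed$diptera_taxon),
                                     unique(df$diptera_taxon))),
    removed_interactions = nrow(removed),
    rows_merged = n_before_merge - nrow(df),
    collapsed_nodes = if (length(collapsed)) do.call(rbind, collapsed)
                      else data.frame(original = character(),
                                      node = character()),
    dispositions = if (length(dispositions)) do.call(rbind, dispositions)
                   else data.frame(side = character(), taxon = character(),
                                   study_id = character(),
                                   action = character(), reason = character()),
    n_input = n_in, n_output = nrow(df)
  )
  stopifnot(log$n_input == log$n_output + log$removed_interactions +
              log$rows_merged)
  list(records = df, log = log)
}
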