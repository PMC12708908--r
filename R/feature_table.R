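new_feature_table <- function(individual, sync, ratings, characteristics,
                              normalized = FALSE) {
  structure(list(individual = individual, sync = sync, ratings = ratings,
                 characteristics = characteristics, normalized = normalized),
            class = "feature_table")
}

#' @exportS3Method base::print
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table: %d individual rows, %d sync rows, %d rating rows%s>\n",
              nrow(x$individual), nrow(x$sync), nrow(x$ratings),
              if (x$normalized) ", baseline-normalized" else ""))
  invisible(x)
}

#' Extract the full feature table from a dyad record
#'
#' Runs peak detection and both feature groups on every interval of a dyad:
#' 20 individual features per participant-interval and 36 synchrony features
#' per dyad-interval, for all 12 intervals (baselines included, so baseline
#' normalization is possible downstream).
#'
#' @param record a `dyad_record` from [generate_dyad()], or a list with
#'   `dyad_id` and `signals` as produced by [read_dyad_signals()] plus
#'   `sampling_rate`, `interval_duration`, `ratings`, `characteristics`.
#' @param grid_rate analysis grid for rate series and synchrony, in Hz.
#' @return a `feature_table` for this single dyad.
#' @export
extract_features <- function(record, grid_rate = 4) {
  fs <- record$sampling_rate
  dur <- record$interval_duration
  ind_rows <- list(); sync_rows <- list()
  for (i in seq_along(record$signals)) {
    iv <- record$signals[[i]]
    for (p in 1:2) {
      f <- individual_features_for_interval(iv[[p]], fs, dur, grid_rate)
      ind_rows[[length(ind_rows) + 1]] <- data.frame(
        dyad_id = record$dyad_id, interval_index = i - 1L, participant = p,
        t(f))
    }
    sf <- synchrony_features_for_interval(iv, fs, dur, grid_rate)
    sync_rows[[length(sync_rows) + 1]] <- data.frame(
      dyad_id = record$dyad_id, interval_index = i - 1L, t(sf))
  }
  new_feature_table(do.call(rbind, ind_rows), do.call(rbind, sync_rows),
                    record$ratings[, c("dyad_id", "interval_index",
                                       "participant", "rater",
                                       "valence", "arousal")],
                    record$characteristics)
}

#' Extract and pool features for a whole cohort
#'
#' @param cohort list of `dyad_record` objects.
#' @param grid_rate analysis grid in Hz.
#' @param verbose print progress per dyad.
#' @return pooled `feature_table`.
#' @export
extract_cohort_features <- function(cohort, grid_rate = 4, verbose = FALSE) {
  parts <- lapply(seq_along(cohort), function(i) {
    if (verbose) message("extracting dyad ", cohort[[i]]$dyad_id)
    extract_features(cohort[[i]], grid_rate)
  })
  new_feature_table(
    do.call(rbind, lapply(parts, `[[`, "individual")),
    do.call(rbind, lapply(parts, `[[`, "sync")),
    do.call(rbind, lapply(parts, `[[`, "ratings")),
    do.call(rbind, lapply(parts, `[[`, "characteristics")))
}

#' Baseline-normalize a feature table
#'
#' Replaces every conversation-interval feature by its value minus the
#' dyad's (and, for individual features, participant's) baseline value:
#' either the first baseline interval (`mode = "first"`) or the average of
#' both baselines (`mode = "mean-of-both"`). Baseline rows are dropped from
#' the result; dyads with a missing baseline are excluded with a warning.
#' Normalizing an already-normalized table is an error.
#'
#' @param table a `feature_table`.
#' @param mode `"first"` or `"mean-of-both"`.
#' @return normalized `feature_table` containing conversation intervals only.
#' @export
normalize_by_baseline <- function(table, mode = c("first", "mean-of-both")) {
  stopifnot(inherits(table, "feature_table"))
  mode <- match.arg(mode)
  if (isTRUE(table$normalized))
    stop("feature table is already baseline-normalized")
  last_idx <- max(table$sync$interval_index)
  base_idx <- if (mode == "first") 0L else c(0L, last_idx)
  norm_block <- function(df, keys) {
    feat_cols <- setdiff(names(df), c("dyad_id", "interval_index", "participant"))
    conv <- df[df$interval_index >= 1 & df$interval_index < last_idx, ]
    bad <- character(0)
    for (d in unique(conv$dyad_id)) {
      keysets <- if ("participant" %in% keys)
        unique(conv$participant[conv$dyad_id == d]) else NA
      for (p in keysets) {
        sel_b <- df$dyad_id == d & df$interval_index %in% base_idx
        sel_c <- conv$dyad_id == d
        if ("participant" %in% keys) {
          sel_b <- sel_b & df$participant == p
          sel_c <- sel_c & conv$participant == p
        }
        if (sum(sel_b) < length(base_idx)) {
          bad <- c(bad, as.character(d))
          next
        }
        base <- colMeans(df[sel_b, feat_cols, drop = FALSE])
        conv[sel_c, feat_cols] <-
          sweep(conv[sel_c, feat_cols, drop = FALSE], 2, base, "-")
      }
    }
    list(df = conv, bad = unique(bad))
  }
  ind <- norm_block(table$individual, c("dyad_id", "participant"))
  syn <- norm_block(table$sync, "dyad_id")
  bad <- union(ind$bad, syn$bad)
  out_ind <- ind$df; out_syn <- syn$df
  if (length(bad) > 0) {
    warning("excluding dyads with missing baseline: ", paste(bad, collapse = ", "))
    out_ind <- out_ind[!out_ind$dyad_id %in% bad, ]
    out_syn <- out_syn[!out_syn$dyad_id %in% bad, ]
  }
  new_feature_table(out_ind, out_syn, table$ratings, table$characteristics,
                    normalized = TRUE)
}

gender_onehot <- function(g, prefix) {
  lev <- c("male", "female", "nonbinary")
  m <- sapply(lev, function(l) as.numeric(g == l))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(NULL, lev))
  colnames(m) <- paste0(prefix, "gender_", lev)
  m
}

characteristic_cols <- function(chars, dyad, participant, prefix = "") {
  row <- chars[chars$dyad_id == dyad & chars$participant == participant, ]
  if (nrow(row) == 0) return(NULL)
  num <- c(age = row$age, cognitive_empathy = row$cognitive_empathy,
           affective_empathy = row$affective_empathy,
           social_anxiety = row$social_anxiety, depression = row$depression)
  names(num) <- paste0(prefix, names(num))
  c(num, gender_onehot(row$gender, prefix)[1, ])
}

#' Build a regression design for one goal
#'
#' Assembles `(input vector, label, unit key)` rows from a (normally
#' baseline-normalized) feature table.
#'
#' Goals 1 and 2 produce one row per participant-interval with that
#' participant's 20 individual features plus the dyad's 36 synchrony features
#' (56 input columns); the partner's individual features are never included.
#' Goal 3 produces one row per dyad-interval with both participants' 20
#' individual features (prefixed `p1_` / `p2_`) plus the 36 synchrony
#' features (76 columns), labelled by the observer stream. Participant
#' characteristics (age, one-hot gender, four trait scores) are appended
#' when `include_characteristics = TRUE`. Rows with a missing label are
#' dropped with a warning.
#'
#' @param table a `feature_table` restricted to conversation intervals.
#' @param goal 1, 2 or 3.
#' @param target `"valence"` or `"arousal"`.
#' @param include_characteristics append characteristics columns.
#' @return data frame with key columns `dyad_id`, `interval_index`,
#'   `participant`, `unit`, a `label` column and the feature columns; feature
#'   names are recorded in attributes `feature_cols` and `sync_cols`.
#' @export
build_design <- function(table, goal, target = c("valence", "arousal"),
                         include_characteristics = FALSE) {
  stopifnot(inherits(table, "feature_table"), goal %in% 1:3)
  target <- match.arg(target)
  ind_cols <- individual_feature_names()
  sync_cols <- synchrony_feature_names()
  rater <- if (goal == 3) "observer" else "self"
  rt <- table$ratings[table$ratings$rater == rater, ]
  conv_ind <- table$individual[table$individual$interval_index %in%
                                 unique(rt$interval_index), ]
  rows <- list()
  if (goal %in% c(1, 2)) {
    for (r in seq_len(nrow(conv_ind))) {
      key <- conv_ind[r, c("dyad_id", "interval_index", "participant")]
      lab <- rt[rt$dyad_id == key$dyad_id &
                  rt$interval_index == key$interval_index &
                  rt$participant == key$participant, target]
      sy <- table$sync[table$sync$dyad_id == key$dyad_id &
                         table$sync$interval_index == key$interval_index, ]
      row <- data.frame(key,
                        unit = paste0(key$dyad_id, ".", key$participant),
                        label = if (length(lab) == 1) lab else NA_real_,
                        conv_ind[r, ind_cols, drop = FALSE],
                        if (nrow(sy) == 1) sy[, sync_cols, drop = FALSE] else
                          as.data.frame(as.list(stats::setNames(
                            rep(NA_real_, length(sync_cols)), sync_cols))))
      if (include_characteristics) {
        ch <- characteristic_cols(table$characteristics, key$dyad_id,
                                  key$participant)
        if (!is.null(ch)) row <- cbind(row, as.data.frame(as.list(ch)))
      }
      rows[[length(rows) + 1]] <- row
    }
  } else {
    sync <- table$sync[table$sync$interval_index %in%
                         unique(rt$interval_index), ]
    for (r in seq_len(nrow(sync))) {
      key <- sync[r, c("dyad_id", "interval_index")]
      lab <- rt[rt$dyad_id == key$dyad_id &
                  rt$interval_index == key$interval_index, target]
      pull_ind <- function(p) {
        sub <- conv_ind[conv_ind$dyad_id == key$dyad_id &
                          conv_ind$interval_index == key$interval_index &
                          conv_ind$participant == p, ind_cols, drop = FALSE]
        if (nrow(sub) != 1)
          sub <- as.data.frame(as.list(stats::setNames(
            rep(NA_real_, length(ind_cols)), ind_cols)))
        names(sub) <- paste0("p", p, "_", ind_cols)
        sub
      }
      row <- data.frame(key, participant = NA_integer_,
                        unit = as.character(key$dyad_id),
                        label = if (length(lab) == 1) lab else NA_real_,
                        pull_ind(1), pull_ind(2),
                        sync[r, sync_cols, drop = FALSE])
      if (include_characteristics) {
        ch <- c(characteristic_cols(table$characteristics, key$dyad_id, 1, "p1_"),
                characteristic_cols(table$characteristics, key$dyad_id, 2, "p2_"))
        if (length(ch) > 0) row <- cbind(row, as.data.frame(as.list(ch)))
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyNA(out$label)) {
    warning("dropping ", sum(is.na(out$label)), " rows with missing labels")
    out <- out[!is.na(out$label), ]
  }
  key_cols <- c("dyad_id", "interval_index", "participant", "unit", "label")
  attr(out, "feature_cols") <- setdiff(names(out), key_cols)
  attr(out, "sync_cols") <- sync_cols
  out
}

#' Write a feature table to delimited text
#'
#' Writes `individual.csv`, `sync.csv`, `ratings.csv`, `characteristics.csv`
#' and a `schema.json` sidecar (column roles and normalization flag) into
#' `dir`.
#'
#' @param table a `feature_table`.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_feature_table <- function(table, dir) {
  stopifnot(inherits(table, "feature_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(table$individual, file.path(dir, "individual.csv"), row.names = FALSE)
  write.csv(table$sync, file.path(dir, "sync.csv"), row.names = FALSE)
  write.csv(table$ratings, file.path(dir, "ratings.csv"), row.names = FALSE)
  write.csv(table$characteristics, file.path(dir, "characteristics.csv"),
            row.names = FALSE)
  schema <- list(
    normalized = table$normalized,
    roles = list(individual = individual_feature_names(),
                 sync = synchrony_feature_names(),
                 characteristic = c("age", "gender", "cognitive_empathy",
                                    "affective_empathy", "social_anxiety",
                                    "depression")))
  jsonlite::write_json(schema, file.path(dir, "schema.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param dir directory holding the four CSV files and `schema.json`.
#' @return a `feature_table`.
#' @export
read_feature_table <- function(dir) {
  schema <- jsonlite::read_json(file.path(dir, "schema.json"))
  new_feature_table(read.csv(file.path(dir, "individual.csv")),
                    read.csv(file.path(dir, "sync.csv")),
                    read.csv(file.path(dir, "ratings.csv")),
                    read.csv(file.path(dir, "characteristics.csv")),
                    normalized = isTRUE(schema$normalized))
}

#' Load deposited feature and rating tables
#'
#' Schema-driven loader for externally deposited extracted-feature tables
#' (delimited text). Column names are mapped onto the package's canonical
#' names via `mapping` (a named character vector `canonical = deposited`),
#' then validated: any missing required column raises a schema error listing
#' the absent names. No signal processing is performed.
#'
#' @param individual_path,sync_path,ratings_path paths to delimited-text
#'   tables; `sync_path` may be `NULL` when synchrony features are absent.
#' @param characteristics_path optional characteristics table.
#' @param mapping optional named character vector renaming deposited columns
#'   to canonical ones.
#' @param sep field separator.
#' @return a `feature_table`.
#' @export
load_deposited_tables <- function(individual_path, sync_path, ratings_path,
                                  characteristics_path = NULL, mapping = NULL,
                                  sep = ",") {
  rd <- function(p) {
    if (is.null(p)) return(NULL)
    df <- read.csv(p, sep = sep)
    if (!is.null(mapping)) {
      for (canon in names(mapping)) {
        hit <- which(names(df) == mapping[[canon]])
        if (length(hit) == 1) names(df)[hit] <- canon
      }
    }
    df
  }
  check <- function(df, need, what) {
    miss <- setdiff(need, names(df))
    if (length(miss) > 0)
      stop("schema error in ", what, ": missing columns ",
           paste(miss, collapse = ", "))
    df
  }
  ind <- check(rd(individual_path),
               c("dyad_id", "interval_index", "participant",
                 individual_feature_names()), "individual features")
  syn <- if (!is.null(sync_path))
    check(rd(sync_path), c("dyad_id", "interval_index",
                           synchrony_feature_names()), "synchrony features")
  else unique(ind[, c("dyad_id", "interval_index")])
  rat <- check(rd(ratings_path),
               c("dyad_id", "interval_index", "participant", "rater",
                 "valence", "arousal"), "ratings")
  bad <- with(rat, valence < 1 | valence > 9 | arousal < 1 | arousal > 9)
  if (any(bad, na.rm = TRUE)) stop("schema error: ratings outside [1, 9]")
  chars <- rd(characteristics_path)
  new_feature_table(ind, syn, rat,
                    if (is.null(chars)) data.frame() else chars)
}
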