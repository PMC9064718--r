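#' Construct a single longitudinal trajectory
#'
#' A trajectory is one subject's ordered sequence of (time, value)
#' measurements for one biomarker, with an optional per-point censoring flag
#' recording values clamped at assay quantitation limits.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param times Numeric vector of measurement times (months); strictly
#'   increasing. Whole-month integers are typical but any real times are
#'   accepted.
#' @param values Numeric vector of measurements, aligned with `times`.
#' @param marker Character scalar naming the biomarker (e.g. `"cd4"`).
#' @param censor_flags Character vector in `c("none", "at_lower_limit",
#'   "at_upper_limit")`, aligned with `times`. Defaults to `"none"`.
#' @return An object of class `trajectory`.
#' @examples
#' trajectory("s1", times = c(0, 6, 12), values = c(480, 455, 430), marker = "cd4")
#' @export
trajectory <- function(subject_id, times, values, marker = "marker",
                       censor_flags = rep("none", length(times))) {
  subject_id <- as.character(subject_id)
  times <- as.numeric(times)
  values <- as.numeric(values)
  censor_flags <- as.character(censor_flags)
  if (length(times) < 1L) {
    stop("trajectory for subject '", subject_id, "' must contain at least one point")
  }
  if (length(values) != length(times) || length(censor_flags) != length(times)) {
    stop("times, values and censor_flags must have equal length for subject '",
         subject_id, "'")
  }
  if (any(diff(times) <= 0)) {
    stop("times must be strictly increasing for subject '", subject_id, "'")
  }
  if (!all(censor_flags %in% c("none", "at_lower_limit", "at_upper_limit"))) {
    stop("invalid censor flag for subject '", subject_id, "'")
  }
  if (any(!is.finite(values))) {
    stop("non-finite value for subject '", subject_id, "'")
  }
  structure(
    list(subject_id = subject_id, marker = as.character(marker),
         times = times, values = values, censor_flags = censor_flags),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> subject", x$subject_id, "marker", x$marker,
      "-", length(x$times), "points, t in [",
      min(x$times), ",", max(x$times), "]\n")
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$times)

#' Construct a profile set
#'
#' A profile set is an ordered collection of [trajectory()] objects sharing a
#' single marker — the per-biomarker "view" used throughout the pipeline.
#' Subject order is stable and explicit: every downstream distance matrix,
#' dendrogram and label vector indexes subjects in this order.
#'
#' @param trajectories List of `trajectory` objects with unique subject ids
#'   and a common marker label.
#' @return An object of class `profile_set`.
#' @export
profile_set <- function(trajectories) {
  stopifnot(is.list(trajectories))
  if (length(trajectories) > 0L) {
    ok <- vapply(trajectories, inherits, logical(1), what = "trajectory")
    if (!all(ok)) stop("all elements must be trajectory objects")
    ids <- vapply(trajectories, function(t) t$subject_id, character(1))
    if (anyDuplicated(ids)) {
      stop("duplicate subject_id in profile set: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    markers <- unique(vapply(trajectories, function(t) t$marker, character(1)))
    if (length(markers) > 1L) {
      stop("all trajectories in a profile set must share one marker; found: ",
           paste(markers, collapse = ", "))
    }
    names(trajectories) <- ids
    marker <- markers
  } else {
    marker <- NA_character_
  }
  structure(list(trajectories = trajectories, marker = marker),
            class = "profile_set")
}

#' @export
length.profile_set <- function(x) length(x$trajectories)

#' @export
print.profile_set <- function(x, ...) {
  cat("<profile_set>", length(x), "subjects, marker", x$marker, "\n")
  invisible(x)
}

#' Subject identifiers of a profile set, in stable order
#' @param set A `profile_set`.
#' @return Character vector of subject ids.
#' @export
subject_ids <- function(set) {
  stopifnot(inherits(set, "profile_set"))
  if (length(set) == 0L) character(0) else names(set$trajectories)
}

#' Attach ground-truth class labels to a profile set
#'
#' Used by the simulation harnesses to score recovered clusterings against
#' known group membership.
#'
#' @param set A `profile_set`.
#' @param labels Vector of class labels, one per subject, aligned with
#'   [subject_ids()].
#' @return An object of class `labeled_profile_set` with elements `profiles`
#'   and `labels` (a named vector).
#' @export
labeled_profile_set <- function(set, labels) {
  stopifnot(inherits(set, "profile_set"))
  if (length(labels) != length(set)) {
    stop("labels must align one-to-one with subjects (", length(set),
         " subjects, ", length(labels), " labels)")
  }
  labels <- stats::setNames(as.vector(labels), subject_ids(set))
  structure(list(profiles = set, labels = labels),
            class = "labeled_profile_set")
}

#' @export
print.labeled_profile_set <- function(x, ...) {
  cat("<labeled_profile_set>", length(x$profiles), "subjects,",
      length(unique(x$labels)), "classes, marker", x$profiles$marker, "\n")
  invisible(x)
}

#' Read longitudinal profiles from a long-format CSV
#'
#' Expects a UTF-8 CSV with header `subject_id,time,marker,value`; missing
#' visits are simply absent rows (no NA sentinel). One [trajectory()] is
#' built per subject with points sorted by time; subject order is the order
#' of first appearance in the file.
#'
#' @param path Path to the CSV file.
#' @param marker Optional marker name to filter on. Required if the file
#'   contains more than one marker.
#' @return A [profile_set()].
#' @export
read_long_csv <- function(path, marker = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       marker = "character"))
  required <- c("subject_id", "time", "marker", "value")
  if (!all(required %in% names(df))) {
    stop("long CSV must have columns ", paste(required, collapse = ", "))
  }
  profile_set_from_df(df, marker = marker)
}

#' Build a profile set from a long-format data frame
#'
#' @param df Data frame with columns `subject_id`, `time`, `marker`, `value`.
#' @inheritParams read_long_csv
#' @return A [profile_set()].
#' @export
profile_set_from_df <- function(df, marker = NULL) {
  if (!is.null(marker)) df <- df[df$marker == marker, , drop = FALSE]
  if (nrow(df) == 0L) return(profile_set(list()))
  markers <- unique(df$marker)
  if (length(markers) > 1L) {
    stop("file contains multiple markers (", paste(markers, collapse = ", "),
         "); supply a marker filter")
  }
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$value))))
  if (length(bad)) {
    stop("non-numeric value at data row ", bad[1])
  }
  df$value <- as.numeric(df$value)
  df$time <- as.numeric(df$time)
  key <- paste(df$subject_id, df$time, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1, ]
    stop("duplicate (subject_id, time) pair: (", d$subject_id, ", ", d$time, ")")
  }
  ids <- unique(df$subject_id)  # order of first appearance
  trajs <- lapply(ids, function(id) {
    rows <- df[df$subject_id == id, , drop = FALSE]
    rows <- rows[order(rows$time), , drop = FALSE]
    trajectory(id, rows$time, rows$value, marker = markers)
  })
  profile_set(trajs)
}

#' Convert a profile set to a long-format data frame
#'
#' @param set A `profile_set`.
#' @return Data frame with columns `subject_id,time,marker,value`.
#' @export
profile_set_to_df <- function(set) {
  stopifnot(inherits(set, "profile_set"))
  if (length(set) == 0L) {
    return(data.frame(subject_id = character(0), time = numeric(0),
                      marker = character(0), value = numeric(0)))
  }
  do.call(rbind, lapply(set$trajectories, function(t) {
    data.frame(subject_id = t$subject_id, time = t$times,
               marker = t$marker, value = t$values,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Write a profile set as long-format CSV
#'
#' Emits the same dialect read by [read_long_csv()]; values are written as
#' plain decimal text via `format(..., digits = 15)`, so a read/write round
#' trip preserves every (subject, time, value) triple.
#'
#' @param set A `profile_set`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_long_csv <- function(set, path) {
  df <- profile_set_to_df(set)
  df$time <- vapply(df$time, format, character(1), digits = 15)
  df$value <- vapply(df$value, format, character(1), digits = 15)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Keep only subjects with a minimum number of visits
#'
#' Typical cohort analyses restrict to subjects with enough follow-up for a
#' trajectory shape to be meaningful (the HIV-style workflow uses 4 visits).
#'
#' @param set A `profile_set`.
#' @param min_visits Minimum number of measurement points to retain a
#'   subject; must be >= 1.
#' @return A `profile_set` with the retained subjects in their original order.
#' @export
filter_min_visits <- function(set, min_visits) {
  stopifnot(inherits(set, "profile_set"), min_visits >= 1)
  keep <- vapply(set$trajectories, function(t) length(t$times) >= min_visits,
                 logical(1))
  profile_set(set$trajectories[keep])
}

#' Log10-transform all values in a profile set
#'
#' Standard preprocessing for viral load before distance calculation. Times
#' and censor flags are unchanged.
#'
#' @param set A `profile_set` with all values strictly positive.
#' @return Transformed `profile_set`.
#' @export
log10_values <- function(set) {
  stopifnot(inherits(set, "profile_set"))
  trajs <- lapply(set$trajectories, function(t) {
    bad <- which(t$values <= 0)
    if (length(bad)) {
      stop("nonpositive value for subject '", t$subject_id,
           "' at time ", t$times[bad[1]])
    }
    t$values <- log10(t$values)
    t
  })
  profile_set(trajs)
}

#' Clamp values at assay quantitation limits
#'
#' Values below `lower` are set to `lower` and flagged `at_lower_limit`;
#' values above `upper` are set to `upper` and flagged `at_upper_limit`.
#' Censored points are clamped and kept, never dropped: the clamped value is
#' what the assay reports and is clustered as observed.
#'
#' @param set A `profile_set`.
#' @param lower,upper Quantitation limits, `lower < upper`. Viral load assays
#'   in the HIV-style workflow use 400 and 750000 copies.
#' @return A `profile_set` with clamped values and updated flags.
#' @export
censor_limits <- function(set, lower, upper) {
  stopifnot(inherits(set, "profile_set"), lower < upper)
  trajs <- lapply(set$trajectories, function(t) {
    lo <- t$values < lower
    hi <- t$values > upper
    t$values[lo] <- lower
    t$values[hi] <- upper
    t$censor_flags[lo] <- "at_lower_limit"
    t$censor_flags[hi] <- "at_upper_limit"
    t
  })
  profile_set(trajs)
}

# value sequences as a plain list, the representation the distance kernels use
values_list <- function(set) {
  lapply(set$trajectories, function(t) t$values)
}
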