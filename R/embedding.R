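#' Stack per-day connectivity vectors into a well feature matrix
#'
#' For one well, each day's pairwise Fisher-z values are flattened in fixed
#' lexicographic pair order (`i < j`) into a row of the feature matrix `A`
#' (`m` days x `k` pairs). Dimensionality reduction is per well because a
#' pair's connectivity is only a meaningful feature within its own well. A
#' pair that is invalid on any day (a silent electrode) is dropped from all
#' rows so columns stay comparable across days; dropped pairs are recorded.
#'
#' @param fc_by_day List of `fc_matrix` objects, one per day, in day order
#'   (day 0 first), all over the same electrode set.
#' @param days Optional day labels (default `0:(m-1)`).
#' @return A `well_trajectory` with `A`, `pairs` (tibble `i`, `j` of kept
#'   pairs), `dropped_pairs`, and empty embedding slots.
#' @export
build_feature_matrix <- function(fc_by_day, days = NULL) {
  stopifnot(is.list(fc_by_day), length(fc_by_day) >= 2,
            all(vapply(fc_by_day, inherits, logical(1), "fc_matrix")))
  sizes <- vapply(fc_by_day, function(f) nrow(f$z), integer(1))
  if (length(unique(sizes)) != 1)
    abort("all days must use the same electrode set")
  m <- length(fc_by_day)
  if (is.null(days)) days <- seq_len(m) - 1L
  long <- lapply(fc_by_day, tidy)
  valid_all <- Reduce(`&`, lapply(long, function(d) d$valid))
  A <- do.call(rbind, lapply(long, function(d) d$z[valid_all]))
  pairs <- long[[1]][valid_all, c("i", "j")]
  structure(list(A = A, pairs = pairs,
                 dropped_pairs = long[[1]][!valid_all, c("i", "j")],
                 days = days, pc_coords = NULL, explained_var = NULL,
                 distances = NULL),
            class = "well_trajectory")
}

#' @export
print.well_trajectory <- function(x, ...) {
  cat(sprintf("<well_trajectory> %d days x %d pair features%s\n",
              nrow(x$A), ncol(x$A),
              if (is.null(x$pc_coords)) "" else ", embedded"))
  invisible(x)
}

#' Project a well's connectivity trajectory onto two principal components
#'
#' Columns of `A` are mean-centered (no variance scaling: all features share
#' Fisher-z units, and scaling would blow up near-constant pairs) and the
#' rows are projected onto the top two right singular directions. With three
#' recordings the centered rows span at most a plane, so the two-component
#' embedding is lossless and between-day distances are preserved exactly.
#'
#' The sign of each component is fixed deterministically: the loading of
#' largest magnitude is made positive.
#'
#' @param traj A `well_trajectory` from [build_feature_matrix()].
#' @param scale_features Also scale columns to unit variance (off by
#'   default).
#' @return The trajectory with `pc_coords` (m x 2) and `explained_var`
#'   filled in.
#' @export
pca_embed <- function(traj, scale_features = FALSE) {
  stopifnot(inherits(traj, "well_trajectory"))
  m <- nrow(traj$A)
  if (m < 2) abort("need at least 2 recordings to embed")
  Ac <- scale(traj$A, center = TRUE, scale = scale_features)
  sv <- svd(Ac)
  d2 <- sv$d^2
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  n_pc <- min(2L, ncol(scores))
  for (p in seq_len(n_pc)) {
    flip <- sign(sv$v[which.max(abs(sv$v[, p])), p])
    if (flip < 0) scores[, p] <- -scores[, p]
  }
  pc <- matrix(0, m, 2)
  pc[, seq_len(n_pc)] <- scores[, seq_len(n_pc)]
  traj$pc_coords <- pc
  traj$explained_var <- if (sum(d2) > 0) d2 / sum(d2) else rep(0, length(d2))
  traj
}

#' Distance of each day's network state to the pre-treatment point
#'
#' Euclidean distance from every row of the two-component embedding to the
#' day-0 row. The same distances computed on the full centered feature rows
#' are returned alongside; for three-day trajectories the two coincide (the
#' plane through three points is captured exactly by two components).
#'
#' @param traj An embedded `well_trajectory` (see [pca_embed()]).
#' @return The trajectory with `distances` (per day, to day 0) and
#'   `distances_full` filled in.
#' @export
trajectory_distances <- function(traj) {
  stopifnot(inherits(traj, "well_trajectory"))
  if (is.null(traj$pc_coords)) abort("run pca_embed() first")
  d0 <- traj$pc_coords[1, ]
  traj$distances <- sqrt(colSums((t(traj$pc_coords) - d0)^2))
  Ac <- scale(traj$A, center = TRUE, scale = FALSE)
  traj$distances_full <- sqrt(colSums((t(Ac) - Ac[1, ])^2))
  traj
}

#' Embed a well and compute distances in one call
#'
#' Convenience chain: [build_feature_matrix()] then [pca_embed()] then
#' [trajectory_distances()].
#'
#' @inheritParams build_feature_matrix
#' @inheritParams pca_embed
#' @return A fully populated `well_trajectory`.
#' @export
embed_well <- function(fc_by_day, days = NULL, scale_features = FALSE) {
  build_feature_matrix(fc_by_day, days) %>%
    pca_embed(scale_features) %>%
    trajectory_distances()
}

#' @export
tidy.well_trajectory <- function(x, ...) {
  out <- tibble(day = x$days)
  if (!is.null(x$pc_coords)) {
    out$pc1 <- x$pc_coords[, 1]
    out$pc2 <- x$pc_coords[, 2]
  }
  if (!is.null(x$distances)) out$dist_to_day0 <- x$distances
  out
}

#' @export
glance.well_trajectory <- function(x, ...) {
  tibble(n_days = nrow(x$A), n_pairs = ncol(x$A),
         n_dropped = nrow(x$dropped_pairs),
         var_explained_2pc = if (is.null(x$explained_var)) NA_real_ else
           sum(x$explained_var[1:min(2, length(x$explained_var))]),
         max_dist = if (is.null(x$distances)) NA_real_ else max(x$distances))
}

#' Compare day-2 trajectory distances between groups
#'
#' Two-sample t-test (with Cohen's d) of the distance-to-baseline values of
#' treated versus control wells, the endpoint quantifying whether treated
#' networks move to a distinct region of connectivity space.
#'
#' @param treated,control Numeric vectors of per-well distances (>= 2 wells
#'   each).
#' @param kind `"pooled"` (Student) or `"welch"`.
#' @return A one-row `stat_result` tibble (see [two_sample_t()]).
#' @export
compare_group_distances <- function(treated, control, kind = "pooled") {
  if (length(treated) < 2 || length(control) < 2)
    abort("need at least 2 wells per group")
  two_sample_t(treated, control, kind = kind)
}

#' Write per-well trajectories as CSV
#'
#' Long CSV with header `well,group,day,pc1,pc2,dist_to_day0`.
#'
#' @param traj_tbl Tibble with columns `well`, `group` and `trajectory`
#'   (list of embedded `well_trajectory` objects), as produced by the MEA
#'   pipeline.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj_tbl, path) {
  long <- traj_tbl %>%
    mutate(td = purrr::map(.data$trajectory, tidy)) %>%
    select("well", "group", "td") %>%
    tidyr::unnest("td")
  utils::write.csv(as.data.frame(long), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
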