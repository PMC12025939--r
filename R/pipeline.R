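# End-to-end orchestration: phantom or NIfTI input -> T2 map -> filter ->
# length parameterization -> profile -> segments -> statistics, for one
# subject or a paired pre/post cohort.

#' Read a multi-echo series from NIfTI files
#'
#' @param files Character vector of per-echo NIfTI paths, ordered as
#'   \code{echo_train}.
#' @param echo_train Echo times in ms, one per file.
#' @return A \code{\link{multi_echo_image}}.  Uses the first volume's
#'   in-plane pixel dimension as the voxel spacing.
#' @export
read_multi_echo <- function(files, echo_train) {
  stopifnot(length(files) == length(echo_train))
  vols <- lapply(files, RNifti::readNifti)
  spacing <- RNifti::pixdim(vols[[1]])[1]
  echoes <- lapply(vols, function(v) {
    a <- as.array(v)
    if (length(dim(a)) > 2L) a <- a[, , 1]
    matrix(as.numeric(a), nrow = dim(a)[1])
  })
  multi_echo_image(echoes, echo_train, voxel_spacing = spacing)
}

#' Write a phantom to NIfTI + JSON files
#'
#' Writes one NIfTI per echo (\code{echo_00.nii.gz}, ...), the tendon mask,
#' the ground-truth T2 field, and a \code{truth.json} carrying the profile
#' specification, seeds, noise sigma, and echo train.
#'
#' @param phantom Result of \code{\link{generate_phantom}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- phantom$image; truth <- phantom$truth
  files <- character(0)
  for (i in seq_along(img$echoes)) {
    f <- file.path(dir, sprintf("echo_%02d.nii.gz", i - 1L))
    RNifti::writeNifti(RNifti::asNifti(img$echoes[[i]],
                                       pixdim = rep(img$voxel_spacing, 2)), f)
    files <- c(files, f)
  }
  fm <- file.path(dir, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(truth$mask$voxels * 1), fm)
  ft <- file.path(dir, "truth_t2.nii.gz")
  t2 <- truth$t2_field; t2[is.na(t2)] <- 0
  RNifti::writeNifti(RNifti::asNifti(t2), ft)
  fj <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    echo_train = img$echo_train,
    profile_spec = truth$config$profile_spec,
    noise_sigma = truth$config$noise_sigma,
    seed = truth$config$seed,
    voxel_spacing = img$voxel_spacing,
    lateral_seed = truth$mask$lateral_seed,
    medial_seed = truth$mask$medial_seed,
    tendon_length_mm = truth$tendon_length_mm
  ), fj, auto_unbox = TRUE, digits = NA)
  invisible(c(files, fm, ft, fj))
}

# wrap a stage so failures carry the stage name
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full single-subject pipeline
#'
#' Executes fit -> filter -> length parameterization -> binning -> segment
#' split -> summaries in order and returns every intermediate product plus
#' a provenance block.
#'
#' @param image A \code{\link{multi_echo_image}}.
#' @param mask A \code{\link{tendon_mask}}.
#' @param method Fit method, \code{"loglinear"} or \code{"nls"}.
#' @param t2_bounds,r2_min Filter settings, see \code{\link{filter_t2_map}}.
#' @param n_bins Profile bins, see \code{\link{bin_profile}}.
#' @param out_dir Optional directory; when given, writes
#'   \code{profile.csv}, \code{segments.json} and \code{manifest.json}.
#' @param subject_id Label recorded in outputs.
#' @return An object of class \code{subject_report}: \code{t2map},
#'   \code{filter}, \code{length_field}, \code{profile}, \code{labels},
#'   \code{segments}, \code{regressions}, \code{provenance}.
#' @export
run_subject <- function(image, mask, method = "loglinear",
                        t2_bounds = c(5, 120), r2_min = 0.7,
                        n_bins = 100L, out_dir = NULL,
                        subject_id = "subject") {
  t2map <- run_stage("fit", compute_t2_map(image, mask = mask, method = method))
  filt <- run_stage("filter", filter_t2_map(t2map, mask, t2_bounds, r2_min))
  lf <- run_stage("parameterize", parameterize_length(mask, image$voxel_spacing))
  prof <- run_stage("bin", bin_profile(t2map, filt, lf, n_bins))
  labels <- run_stage("segment", split_segments(lf))
  segs <- run_stage("summaries", segment_means(t2map, filt, labels))
  regs <- run_stage("regression", segment_regressions(prof))
  prov <- list(subject_id = subject_id, method = method,
               t2_bounds = t2_bounds, r2_min = r2_min, n_bins = n_bins,
               n_mask = filt$n_mask, n_kept = filt$n_kept,
               removed = as.list(filt$removed),
               tendon_length_mm = lf$tendon_length_mm,
               package_version = as.character(utils::packageVersion("tendonT2")))
  rep <- structure(list(t2map = t2map, filter = filt, length_field = lf,
                        profile = prof, labels = labels, segments = segs,
                        regressions = regs, provenance = prov),
                   class = "subject_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(prof),
                     file.path(out_dir, "profile.csv"), row.names = FALSE)
    jsonlite::write_json(list(segments = segs, provenance = prov),
                         file.path(out_dir, "segments.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(prov, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  rep
}

#' @export
print.subject_report <- function(x, ...) {
  cat(sprintf("<subject_report> %s: %d/%d voxels kept, tendon length %.1f mm\n",
              x$provenance$subject_id, x$provenance$n_kept,
              x$provenance$n_mask, x$provenance$tendon_length_mm))
  print(x$segments)
  invisible(x)
}

#' Average subject profiles with equal subject weight
#'
#' Bin-wise mean of per-subject profiles, weighting each subject equally
#' (not voxel-pooled), so large tendons do not dominate the group curve.
#' Bins empty for a subject are omitted from that bin's average.
#'
#' @param profiles List of \code{t2_profile} objects on a common bin grid.
#' @return A \code{t2_profile} whose \code{bin_counts} hold the number of
#'   contributing subjects per bin.
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  nb <- profiles[[1]]$n_bins
  ok <- vapply(profiles, function(p) inherits(p, "t2_profile") && p$n_bins == nb,
               logical(1))
  if (!all(ok)) stop("profiles must share one bin grid", call. = FALSE)
  M <- vapply(profiles, function(p) {
    m <- p$bin_means
    m[p$bin_counts == 0] <- NA_real_
    m
  }, numeric(nb))
  M <- matrix(M, nrow = nb)
  n_sub <- rowSums(!is.na(M))
  means <- rowMeans(M, na.rm = TRUE)
  means[n_sub == 0] <- NA_real_
  structure(list(bin_centers = profiles[[1]]$bin_centers,
                 bin_means = means, bin_counts = n_sub,
                 n_bins = nb),
            class = "t2_profile")
}

#' Simulate a paired pre/post phantom cohort
#'
#' Generates one phantom pair per subject.  Between-subject variability
#' comes from independent noise realizations and a subject-level random T2
#' offset (shared by that subject's two visits) on top of the preset
#' profiles.
#'
#' @param n_subjects Number of paired subjects.
#' @param pre_preset,post_preset Profile preset names, see
#'   \code{\link{profile_preset}}.
#' @param noise_sigma Rician sigma in signal units (default 2 % of S0).
#' @param subject_sd Standard deviation (ms) of the subject-level T2
#'   offset.
#' @param seed Integer master seed.
#' @param ... Further arguments to \code{\link{phantom_config}}.
#' @return List of subjects, each a list with \code{pre} and \code{post}
#'   phantom results and \code{subject_id}.
#' @export
simulate_cohort <- function(n_subjects, pre_preset = "tendinosis_before",
                            post_preset = "tendinosis_after",
                            noise_sigma = 20, subject_sd = 2, seed = 1L, ...) {
  stopifnot(n_subjects >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  offsets <- rnorm(n_subjects, 0, subject_sd)
  sub_seeds <- sample.int(2^30, 2 * n_subjects)
  shift_spec <- function(preset, off) {
    sp <- profile_preset(preset)
    sp$intercept <- sp$intercept + off
    sp
  }
  lapply(seq_len(n_subjects), function(i) {
    pre_cfg <- phantom_config(profile_spec = shift_spec(pre_preset, offsets[i]),
                              noise_sigma = noise_sigma,
                              seed = sub_seeds[2 * i - 1L], ...)
    post_cfg <- phantom_config(profile_spec = shift_spec(post_preset, offsets[i]),
                               noise_sigma = noise_sigma,
                               seed = sub_seeds[2 * i], ...)
    list(subject_id = sprintf("S%02d", i),
         pre = generate_phantom(pre_cfg),
         post = generate_phantom(post_cfg))
  })
}

#' Run a paired pre/post cohort analysis
#'
#' Processes every subject's two visits through \code{\link{run_subject}},
#' averages profiles per visit with equal subject weight, fits per-segment
#' regressions to both group profiles, compares them segment-wise with the
#' Chow test, and compares paired per-subject segment means with the
#' Wilcoxon signed-rank test.
#'
#' @param subjects List as returned by \code{\link{simulate_cohort}}: per
#'   subject a list with \code{subject_id} and \code{pre}/\code{post}
#'   elements each carrying \code{image} and a truth or mask; alternatively
#'   supply \code{image} and \code{mask} per visit directly.
#' @param ... Pipeline settings forwarded to \code{\link{run_subject}}.
#' @return An object of class \code{cohort_report}: \code{table} (one row
#'   per subject x visit x segment), \code{group_profiles} (pre/post
#'   averaged \code{t2_profile}s), \code{regression_table} (per segment and
#'   visit: slope, intercept, Chow p), \code{wilcoxon} (per segment:
#'   statistic, p), \code{reports} (per-subject pipeline outputs).
#' @export
run_cohort <- function(subjects, ...) {
  if (length(subjects) < 4L) {
    stop("group statistics need at least 4 paired subjects", call. = FALSE)
  }
  missing_visit <- vapply(subjects, function(s)
    is.null(s$pre) || is.null(s$post), logical(1))
  if (any(missing_visit)) {
    ids <- vapply(which(missing_visit), function(i)
      if (!is.null(subjects[[i]]$subject_id)) subjects[[i]]$subject_id
      else as.character(i), character(1))
    stop("unpaired subjects (missing pre or post visit): ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  visit_input <- function(v) {
    mask <- if (!is.null(v$mask)) v$mask else v$truth$mask
    list(image = v$image, mask = mask)
  }
  reports <- lapply(subjects, function(s) {
    pre_in <- visit_input(s$pre); post_in <- visit_input(s$post)
    list(subject_id = s$subject_id,
         pre = run_subject(pre_in$image, pre_in$mask,
                           subject_id = paste0(s$subject_id, "_pre"), ...),
         post = run_subject(post_in$image, post_in$mask,
                            subject_id = paste0(s$subject_id, "_post"), ...))
  })

  rows <- do.call(rbind, lapply(reports, function(r) {
    do.call(rbind, lapply(c("pre", "post"), function(v) {
      seg <- r[[v]]$segments
      data.frame(subject = r$subject_id, visit = v,
                 segment = as.character(seg$segment),
                 mean_t2 = seg$mean_t2, sd_t2 = seg$sd_t2,
                 n_voxels = seg$n_voxels, stringsAsFactors = FALSE)
    }))
  }))

  group_profiles <- list(
    pre = average_profiles(lapply(reports, function(r) r$pre$profile)),
    post = average_profiles(lapply(reports, function(r) r$post$profile))
  )
  regs <- lapply(group_profiles, segment_regressions)

  seg_names <- c("lateral", "middle", "medial")
  seg_xy <- function(profile, s) {
    keep <- segment_of(profile$bin_centers) == s & profile$bin_counts > 0
    list(x = profile$bin_centers[keep], y = profile$bin_means[keep])
  }
  reg_rows <- lapply(seg_names, function(s) {
    chow <- chow_test(seg_xy(group_profiles$pre, s),
                      seg_xy(group_profiles$post, s))
    data.frame(segment = s,
               slope_before = regs$pre[[s]]$slope,
               intercept_before = regs$pre[[s]]$intercept,
               slope_after = regs$post[[s]]$slope,
               intercept_after = regs$post[[s]]$intercept,
               chow_f = chow$f_stat, chow_p = chow$p_value,
               stringsAsFactors = FALSE)
  })
  regression_table <- do.call(rbind, reg_rows)

  wilcoxon <- do.call(rbind, lapply(seg_names, function(s) {
    pre_m <- rows$mean_t2[rows$visit == "pre" & rows$segment == s]
    post_m <- rows$mean_t2[rows$visit == "post" & rows$segment == s]
    wt <- wilcoxon_signed_rank(pre_m, post_m)
    data.frame(segment = s, statistic = wt$statistic, p_value = wt$p_value,
               n = wt$n, stringsAsFactors = FALSE)
  }))

  structure(list(table = rows, group_profiles = group_profiles,
                 regression_table = regression_table, wilcoxon = wilcoxon,
                 reports = reports),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d paired subjects\n", length(x$reports)))
  cat("\nPer-segment regression (group profiles):\n")
  print(x$regression_table, row.names = FALSE, digits = 4)
  cat("\nWilcoxon signed-rank on paired segment means:\n")
  print(x$wilcoxon, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Mean absolute difference between two profiles
#'
#' Average of |difference of bin means| over bins nonempty in both
#' profiles; used to quantify how close a recovered profile is to a
#' reference curve.
#'
#' @param a,b \code{t2_profile} objects on a common bin grid.
#' @return Mean absolute difference in ms.
#' @export
profile_distance <- function(a, b) {
  stopifnot(inherits(a, "t2_profile"), inherits(b, "t2_profile"),
            a$n_bins == b$n_bins)
  keep <- a$bin_counts > 0 & b$bin_counts > 0
  if (!any(keep)) stop("no bins nonempty in both profiles", call. = FALSE)
  mean(abs(a$bin_means[keep] - b$bin_means[keep]))
}

#' Evaluate a piecewise-linear profile specification as a t2_profile
#'
#' Convenience for comparing recovered profiles against a preset: evaluates
#' the piecewise-linear T2(x) at the centers of an n-bin grid.
#'
#' @param profile_spec See \code{\link{make_profile_function}}.
#' @param n_bins Bin count of the target grid.
#' @return A \code{t2_profile} with unit counts.
#' @export
spec_as_profile <- function(profile_spec, n_bins = 100L) {
  f <- make_profile_function(profile_spec)
  centers <- (seq_len(n_bins) - 0.5) * (100 / n_bins)
  structure(list(bin_centers = centers, bin_means = f(centers),
                 bin_counts = rep(1L, n_bins), n_bins = as.integer(n_bins)),
            class = "t2_profile")
}
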