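# End-to-end pipeline: input pairing, per-patient feature extraction and
# deviation assessment, cohort evaluation, interim-result persistence, run
# log, and the significance-colored overview plot.

#' Run configuration
#'
#' @param pre,post Paths: either two NIfTI files (single patient) or two
#'   directories of patient volumes matched by basename.
#' @param out Output directory (created if needed; must be writable).
#' @param masks_pre,masks_post Optional mask inputs. Single-patient mode: a
#'   directory of binary masks or a label image. Directory mode: a directory
#'   containing per-patient subdirectories of binary masks, or per-patient
#'   label images `<patient_id>.nii(.gz)`.
#' @param label_table Label-to-name table (path or data.frame) for the
#'   label-image mask dialect; shared across patients.
#' @param pairs Optional two-column tab-separated file (pre basename, post
#'   basename) overriding basename matching.
#' @param bonferroni Add the Bonferroni column to the evaluation table.
#' @param keep_interim Keep per-patient feature tables and derived tissue
#'   masks on disk.
#' @param derive_tissue Derive body-composition tissue masks from any
#'   supplied region masks (see [body_regions()]).
#' @param plot_format `"svg"` (vector, default) or `"png"`.
#' @param seed Integer recorded in the run log; the analysis itself is
#'   deterministic.
#' @return An object of class `run_config`.
#' @export
run_config <- function(pre, post, out, masks_pre = NULL, masks_post = NULL,
                       label_table = NULL, pairs = NULL, bonferroni = FALSE,
                       keep_interim = TRUE, derive_tissue = TRUE,
                       plot_format = c("svg", "png"), seed = NULL) {
  plot_format <- match.arg(plot_format)
  pre_is_dir <- dir.exists(pre)
  post_is_dir <- dir.exists(post)
  if (pre_is_dir != post_is_dir) {
    stop("pre and post must both be files or both be directories",
         call. = FALSE)
  }
  structure(list(pre = pre, post = post, out = out, masks_pre = masks_pre,
                 masks_post = masks_post, label_table = label_table,
                 pairs = pairs, bonferroni = isTRUE(bonferroni),
                 keep_interim = isTRUE(keep_interim),
                 derive_tissue = isTRUE(derive_tissue),
                 plot_format = plot_format, seed = seed,
                 directory_mode = pre_is_dir),
            class = "run_config")
}

#' Pair patient volumes across two directories
#'
#' Files are matched by identical basename (extensions stripped); the shared
#' basename becomes the patient id. Unmatched files are skipped and reported
#' via the `"skipped"` attribute. An optional mapping file overrides name
#' matching.
#'
#' @param pre_dir,post_dir Directories of NIfTI volumes.
#' @param pairs Optional path to a two-column tab-separated file (pre
#'   basename, post basename, extensions optional).
#' @return A data.frame with columns `patient_id`, `pre_file`, `post_file`;
#'   attribute `skipped` lists unmatched basenames.
#' @export
pair_inputs <- function(pre_dir, post_dir, pairs = NULL) {
  if (!dir.exists(pre_dir)) stop("not a directory: ", pre_dir, call. = FALSE)
  if (!dir.exists(post_dir)) stop("not a directory: ", post_dir, call. = FALSE)
  pre_files <- sort(list.files(pre_dir, pattern = "\\.nii(\\.gz)?$",
                               full.names = TRUE))
  post_files <- sort(list.files(post_dir, pattern = "\\.nii(\\.gz)?$",
                                full.names = TRUE))
  pre_ids <- strip_nii_ext(basename(pre_files))
  post_ids <- strip_nii_ext(basename(post_files))

  if (!is.null(pairs)) {
    map <- utils::read.table(pairs, header = FALSE, sep = "\t",
                             col.names = c("pre", "post"),
                             stringsAsFactors = FALSE)
    map$pre <- strip_nii_ext(map$pre)
    map$post <- strip_nii_ext(map$post)
    keep <- map$pre %in% pre_ids & map$post %in% post_ids
    matched <- data.frame(
      patient_id = map$pre[keep],
      pre_file = pre_files[match(map$pre[keep], pre_ids)],
      post_file = post_files[match(map$post[keep], post_ids)],
      stringsAsFactors = FALSE
    )
    skipped <- c(setdiff(pre_ids, map$pre[keep]),
                 setdiff(post_ids, map$post[keep]))
  } else {
    common <- intersect(pre_ids, post_ids)
    matched <- data.frame(
      patient_id = common,
      pre_file = pre_files[match(common, pre_ids)],
      post_file = post_files[match(common, post_ids)],
      stringsAsFactors = FALSE
    )
    skipped <- c(setdiff(pre_ids, common), setdiff(post_ids, common))
  }
  if (nrow(matched) == 0L) {
    stop("no matched pre/post volume pairs between '", pre_dir, "' and '",
         post_dir, "'", call. = FALSE)
  }
  matched <- matched[order(matched$patient_id), , drop = FALSE]
  rownames(matched) <- NULL
  attr(matched, "skipped") <- sort(unique(skipped))
  matched
}

.mask_input_for_patient <- function(root, patient_id, directory_mode) {
  if (is.null(root)) return(NULL)
  if (!directory_mode) return(root)
  sub <- file.path(root, patient_id)
  if (dir.exists(sub)) return(sub)
  for (ext in c(".nii.gz", ".nii")) {
    f <- file.path(root, paste0(patient_id, ext))
    if (file.exists(f)) return(f)
  }
  NULL
}

.load_masks <- function(path, ct, label_table) {
  if (is.null(path)) return(NULL)
  read_mask_set(path, ct, label_table = label_table)
}

.process_patient <- function(pid, pre_file, post_file, config, interim_dir,
                             log) {
  tables <- list()
  for (cond in c("pre", "post")) {
    f <- if (cond == "pre") pre_file else post_file
    ct <- read_ct(f, patient_id = pid, condition = cond)
    mroot <- if (cond == "pre") config$masks_pre else config$masks_post
    mpath <- .mask_input_for_patient(mroot, pid, config$directory_mode)
    if (is.null(mpath)) {
      stop("no masks found for patient '", pid, "' (", cond, ")",
           call. = FALSE)
    }
    masks <- .load_masks(mpath, ct, config$label_table)
    sets <- list(masks)
    if (config$derive_tissue &&
        any(names(masks$masks) %in% body_regions())) {
      region_names <- intersect(names(masks$masks), body_regions())
      regions <- mask_set(masks$masks[region_names], source = "anatomical")
      tissue <- derive_tissue_masks(ct, regions)
      sets <- c(sets, list(tissue))
      if (config$keep_interim && length(tissue$masks) > 0L) {
        write_mask_set(tissue,
                       file.path(interim_dir, "tissue_masks", pid, cond),
                       affine = ct$affine)
      }
      log(sprintf("patient %s [%s]: derived %d tissue masks from %d regions",
                  pid, cond, length(tissue$masks), length(region_names)))
    }
    feats <- extract_features(ct, sets)
    if (config$keep_interim) {
      write_feature_csv(feats, file.path(interim_dir,
                                         sprintf("features_%s_%s.csv",
                                                 pid, cond)))
    }
    log(sprintf("patient %s [%s]: %d structures, %d feature records",
                pid, cond, length(unique(feats$structure)), nrow(feats)))
    tables[[cond]] <- feats
  }
  paired <- pair_features(tables$pre, tables$post)
  dropped <- attr(paired, "dropped")
  if (length(dropped) > 0L) {
    log(sprintf("patient %s: excluded %d non-pairwise feature(s): %s",
                pid, length(dropped), paste(dropped, collapse = ", ")))
  }
  compute_deviations(paired)
}

#' Run the full trend-analysis pipeline
#'
#' Reads paired pre/post CT volumes plus structure masks, derives tissue
#' masks where region masks are available, extracts per-structure features,
#' computes per-patient deviations, and writes the cohort evaluation table,
#' the overview plot, per-patient CSVs, and a run log into the output
#' directory. On a fatal error, partial outputs are retained and a MANIFEST
#' file records the incompleteness before the error is re-signalled.
#'
#' @param config A [run_config].
#' @return Invisibly, a list with elements `evaluation` (data.frame),
#'   `deviations` (data.frame), `pairs` (pairing table), and `out`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out) ||
      file.access(config$out, mode = 2) != 0L) {
    stop("output directory is not writable: ", config$out, call. = FALSE)
  }
  interim_dir <- file.path(config$out, "interim")
  if (config$keep_interim) {
    dir.create(interim_dir, recursive = TRUE, showWarnings = FALSE)
  }
  log_path <- file.path(config$out, "run.log")
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                                      " | ", msg))
  }
  log(sprintf("trendkit %s | R %s",
              as.character(utils::packageVersion("trendkit")),
              paste(R.version$major, R.version$minor, sep = ".")))
  log(sprintf("settings: bonferroni=%s keep_interim=%s derive_tissue=%s seed=%s",
              config$bonferroni, config$keep_interim, config$derive_tissue,
              if (is.null(config$seed)) "none" else config$seed))

  result <- tryCatch({
    if (config$directory_mode) {
      pairs <- pair_inputs(config$pre, config$post, pairs = config$pairs)
      skipped <- attr(pairs, "skipped")
      if (length(skipped) > 0L) {
        log(sprintf("skipped %d unmatched volume(s): %s", length(skipped),
                    paste(skipped, collapse = ", ")))
      }
    } else {
      pid <- strip_nii_ext(basename(config$pre))
      pairs <- data.frame(patient_id = pid, pre_file = config$pre,
                          post_file = config$post, stringsAsFactors = FALSE)
    }
    log(sprintf("paired %d patient(s): %s", nrow(pairs),
                paste(pairs$patient_id, collapse = ", ")))

    dev_list <- lapply(seq_len(nrow(pairs)), function(i) {
      .process_patient(pairs$patient_id[i], pairs$pre_file[i],
                       pairs$post_file[i], config, interim_dir, log)
    })
    deviations <- do.call(rbind, dev_list)
    rownames(deviations) <- NULL
    if (config$keep_interim) {
      for (i in seq_len(nrow(pairs))) {
        pid <- pairs$patient_id[i]
        write_deviation_csv(
          deviations[deviations$patient_id == pid, , drop = FALSE],
          file.path(interim_dir, sprintf("deviations_%s.csv", pid)))
      }
    }

    evaluation <- evaluate_cohort(deviations, bonferroni = config$bonferroni)
    write_evaluation_csv(evaluation, file.path(config$out, "evaluation.csv"))
    plot_file <- file.path(config$out,
                           paste0("overview.", config$plot_format))
    plot_overview(evaluation, plot_file, format = config$plot_format)
    log(sprintf("evaluated %d feature(s) across %d patient(s); %d significant at p<0.05",
                nrow(evaluation), nrow(pairs),
                sum(evaluation$p < 0.05)))
    list(evaluation = evaluation, deviations = deviations, pairs = pairs,
         out = config$out)
  }, error = function(e) {
    log(paste("FATAL:", conditionMessage(e)))
    writeLines(c("status: INCOMPLETE",
                 paste("error:", conditionMessage(e)),
                 "note: partial outputs retained"),
               file.path(config$out, "MANIFEST"))
    writeLines(log_lines, log_path)
    stop(e)
  })

  writeLines(c("status: COMPLETE",
               "outputs: evaluation.csv, overview plot, run.log, interim/"),
             file.path(config$out, "MANIFEST"))
  writeLines(log_lines, log_path)
  invisible(result)
}

#' Significance-colored overview plot
#'
#' One mark per evaluated feature, positioned by its macro-averaged relative
#' difference and colored by significance class (`ns`, `p<0.05`, `p<0.01`).
#' All three classes always appear in the legend. Features are ordered
#' deterministically (structure, then metric).
#'
#' @param evaluations Output of [evaluate_cohort()].
#' @param out_path Output image path.
#' @param format `"svg"` or `"png"`.
#' @return `out_path`, invisibly.
#' @export
plot_overview <- function(evaluations, out_path, format = c("svg", "png")) {
  format <- match.arg(format)
  if (nrow(evaluations) < 1L) {
    stop("nothing to plot: no evaluation rows", call. = FALSE)
  }
  df <- evaluations[order(evaluations$structure, evaluations$metric), ,
                    drop = FALSE]
  df$feature <- paste(df$structure, df$metric, sep = " : ")
  df$feature <- factor(df$feature, levels = rev(df$feature))
  df$significance <- factor(df$significance,
                            levels = c("ns", "p<0.05", "p<0.01"))
  palette <- c("ns" = "grey60", "p<0.05" = "#fdae61", "p<0.01" = "#d7191c")

  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_rel_diff_pct,
                                        y = .data$feature,
                                        color = .data$significance)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        color = "grey75") +
    ggplot2::geom_point(size = 2.4) +
    ggplot2::scale_color_manual(values = palette, drop = FALSE,
                                name = "paired t-test") +
    ggplot2::labs(x = "mean relative difference (%)", y = NULL,
                  title = "Radiomic feature dynamics (post vs pre)") +
    ggplot2::theme_minimal(base_size = 10)

  height <- max(3, 0.18 * nrow(df) + 1.5)
  if (format == "svg") {
    grDevices::svg(out_path, width = 8, height = height)
  } else {
    grDevices::png(out_path, width = 8, height = height, units = "in",
                   res = 150)
  }
  on.exit(grDevices::dev.off())
  print(p)
  invisible(out_path)
}
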