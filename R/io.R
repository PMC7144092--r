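# Tabular readers/writers for the assay formats and a pipeline driver.
# All tabular I/O is UTF-8 TSV/CSV with explicit headers and "." as the
# decimal mark, so fixtures round-trip bit-exactly.

.read_checked <- function(path, required, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "\"",
                          fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  df
}

.check_numeric_col <- function(df, cols, path) {
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop("non-numeric value in column '", cl, "' of ", path,
           " at data row(s) ", paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  df
}

#' Read countercurrent tube counts
#'
#' TSV with columns genotype, replicate, N0..N5.
#' @param path File path.
#' @return Validated data frame.
#' @export
read_tube_counts <- function(path) {
  tube_cols <- paste0("N", 0:5)
  df <- .read_checked(path, c("genotype", "replicate", tube_cols))
  .check_numeric_col(df, tube_cols, path)
  bad <- which(apply(df[tube_cols], 1L, function(r)
    any(r < 0 | r != round(r)) || sum(r) < 1))
  if (length(bad))
    stop("invalid tube counts in ", path, " at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  df
}

#' Read a trajectory file
#'
#' CSV with columns fly_id, frame, x, y; frames must be strictly increasing
#' within each fly.
#' @param path File path.
#' @return Validated data frame.
#' @export
read_trajectory <- function(path) {
  df <- .read_checked(path, c("fly_id", "frame", "x", "y"), sep = ",")
  .check_numeric_col(df, c("frame", "x", "y"), path)
  for (fid in unique(df$fly_id)) {
    fr <- df$frame[df$fly_id == fid]
    if (any(diff(fr) <= 0))
      stop("frames not strictly increasing for fly ", fid, " in ", path)
  }
  df
}

#' Read chamber geometry from a YAML/key-value config
#'
#' Accepts a small config with keys xc, yc, radius and optionally
#' inner_ratio or inner_radius, in either "key: value" or "key = value"
#' lines.
#' @param path File path.
#' @return A \code{\link{chamber_geometry}} object.
#' @export
read_geometry <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[:=]", perl = TRUE)
  if (any(lengths(kv) != 2L)) stop("cannot parse geometry config ", path)
  vals <- stats::setNames(as.numeric(trimws(vapply(kv, `[`, "", 2L))),
                          trimws(vapply(kv, `[`, "", 1L)))
  need <- c("xc", "yc", "radius")
  if (!all(need %in% names(vals)))
    stop("geometry config must define ", paste(need, collapse = ", "))
  chamber_geometry(vals[["xc"]], vals[["yc"]], vals[["radius"]],
                   inner_ratio = if ("inner_ratio" %in% names(vals))
                     vals[["inner_ratio"]] else 0.743,
                   inner_radius = if ("inner_radius" %in% names(vals))
                     vals[["inner_radius"]] else NULL)
}

#' Read seizure time-courses
#'
#' TSV with columns fly_id, genotype, replicate and bin_0..bin_23 (0/1).
#' @param path File path.
#' @return Validated data frame.
#' @export
read_seizure <- function(path) {
  df <- .read_checked(path, c("fly_id", "genotype", "replicate"))
  bins <- grep("^bin_", names(df), value = TRUE)
  if (length(bins) == 0L) stop("no bin_* columns in ", path)
  .check_numeric_col(df, bins, path)
  if (!all(as.matrix(df[bins]) %in% c(0, 1)))
    stop("seizure states must be 0/1 in ", path)
  df
}

#' Read recovery times
#'
#' TSV with columns fly_id, genotype, time_s and optional censored flag.
#' @param path File path.
#' @return Validated data frame (censored coerced to logical, default FALSE).
#' @export
read_recovery <- function(path) {
  df <- .read_checked(path, c("fly_id", "genotype", "time_s"))
  .check_numeric_col(df, "time_s", path)
  if (any(df$time_s < 0)) stop("negative recovery time in ", path)
  df$censored <- if ("censored" %in% names(df)) as.logical(df$censored) else FALSE
  df
}

#' Read a penetrance screen table (printed-percentage layout)
#'
#' TSV mirroring the published table layout: label, scored and one printed
#' percentage column per trait (default wings_percent, thorax_percent).
#' Affected counts are reconstructed with \code{\link{reconstruct_counts}};
#' a \code{<trait>_consistent} flag records whether the reconstruction
#' reproduces the printed percentage.
#'
#' @param path File path.
#' @param traits Trait names (default c("wings", "thorax")).
#' @return Data frame with label, scored, per-trait counts and consistency
#'   flags.
#' @export
read_phenotype_table <- function(path, traits = c("wings", "thorax")) {
  pct_cols <- paste0(traits, "_percent")
  df <- .read_checked(path, c("label", "scored", pct_cols))
  .check_numeric_col(df, c("scored", pct_cols), path)
  out <- df[c("label", "scored")]
  for (tr in traits) {
    rc <- reconstruct_counts(df$scored, df[[paste0(tr, "_percent")]])
    out[[tr]] <- rc$count
    out[[paste0(tr, "_percent")]] <- df[[paste0(tr, "_percent")]]
    out[[paste0(tr, "_consistent")]] <- rc$consistent
  }
  out
}

#' Read a viability/fertility table
#'
#' TSV with columns genotype, total, balancer_class, mutant_class,
#' total_tested, sterile, fertile.
#' @param path File path.
#' @return Validated data frame.
#' @export
read_viability_table <- function(path) {
  need <- c("genotype", "total", "balancer_class", "mutant_class",
            "total_tested", "sterile", "fertile")
  df <- .read_checked(path, need)
  .check_numeric_col(df, need[-1], path)
  if (any(df$balancer_class + df$mutant_class != df$total))
    stop("class counts must sum to total in ", path)
  if (any(df$sterile + df$fertile != df$total_tested))
    stop("sterile + fertile must equal total_tested in ", path)
  df
}

#' Read a counts matrix
#'
#' TSV: first column gene id, remaining columns integer counts per sample.
#' @param path File path.
#' @return Integer matrix with gene rownames.
#' @export
read_counts_matrix <- function(path) {
  df <- .read_checked(path, "gene")
  m <- as.matrix(df[setdiff(names(df), "gene")])
  if (anyNA(m) || any(m < 0)) stop("counts must be non-negative in ", path)
  rownames(m) <- df$gene
  m
}

#' Read a design table
#'
#' TSV with columns sample, condition, replicate.
#' @param path File path.
#' @return Validated data frame.
#' @export
read_design <- function(path) {
  .read_checked(path, c("sample", "condition", "replicate"))
}

#' Write a table as UTF-8 TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @export
write_tsv_out <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Run the analysis pipeline on a set of input files
#'
#' Executes the selected stages over file inputs and writes one TSV result
#' per stage into \code{out_dir}. Stage errors are re-raised with the stage
#' name.
#'
#' @param stages Character vector from \code{c("climbing", "tables")}
#'   selecting which stages to run (those with purely tabular inputs).
#' @param tube_counts Path to countercurrent TSV (for "climbing").
#' @param control Control genotype/label.
#' @param screen_table Path to printed-percentage screen TSV (for "tables").
#' @param control_label Label of the control row in the screen table.
#' @param alpha Significance level.
#' @param out_dir Output directory (created if absent).
#' @return Named list of stage results, invisibly.
#' @export
run_pipeline <- function(stages, tube_counts = NULL, control = NULL,
                         screen_table = NULL, control_label = "No deficiency",
                         alpha = 0.05, out_dir = tempdir()) {
  known <- c("climbing", "tables")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  run_stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("stage '", name, "': ",
                                      conditionMessage(e), call. = FALSE))
  }
  if ("climbing" %in% stages) {
    results$climbing <- run_stage("climbing", {
      runs <- read_tube_counts(tube_counts)
      rep <- compare_climbing(runs, control = control)
      write_tsv_out(rep$summary, file.path(out_dir, "climbing_summary.tsv"))
      write_tsv_out(rep$dunn, file.path(out_dir, "climbing_dunn.tsv"))
      rep
    })
  }
  if ("tables" %in% stages) {
    results$tables <- run_stage("tables", {
      tab <- read_phenotype_table(screen_table)
      ctrl <- tab[tab$label == control_label, , drop = FALSE]
      if (nrow(ctrl) != 1L) stop("control label '", control_label, "' not found")
      recs <- tab[tab$label != control_label, , drop = FALSE]
      rep <- screen_report(recs, ctrl, alpha = alpha)
      write_tsv_out(as.data.frame(rep), file.path(out_dir, "screen_report.tsv"))
      rep
    })
  }
  invisible(results)
}
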