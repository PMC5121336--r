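#' Parse "A01"-style well labels
#'
#' @param well character vector, row letter + 2-digit column (1-based).
#' @param rows allowed row letters (default A-P, 384-well geometry).
#' @param max_col largest allowed column (default 24).
#' @return data frame with `row` (letter) and `col` (integer).
#' @export
parse_well_label <- function(well, rows = LETTERS[1:16], max_col = 24L) {
  ok <- grepl("^[A-Z][0-9]{2}$", well)
  if (any(!ok)) {
    stop("malformed well label(s): ", paste(utils::head(well[!ok]), collapse = ", "))
  }
  r <- substr(well, 1, 1)
  cl <- as.integer(substr(well, 2, 3))
  bad <- !(r %in% rows) | cl < 1L | cl > max_col
  if (any(bad)) {
    stop("well label(s) outside plate geometry (rows ",
         rows[1], "-", rows[length(rows)], ", cols 1-", max_col, "): ",
         paste(utils::head(well[bad]), collapse = ", "))
  }
  data.frame(row = r, col = cl, stringsAsFactors = FALSE)
}

.required_well_cols <- c("plate_id", "replicate", "well", "role", "gene_id",
                         "sirna_id", "intensity", "cell_count",
                         "dead_fraction")

# comma- or tab-separated, header mandatory, "#" lines are metadata
.read_delim <- function(path) {
  first <- readLines(path, n = 20L)
  first <- first[!startsWith(first, "#")]
  if (!length(first)) stop("read: file ", path, " has no data rows")
  sep <- if (grepl("\t", first[1])) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Read and validate a screen well table
#'
#' Delimited text (comma- or tab-separated), header required, one row per
#' well with columns `plate_id`, `replicate`, `well` ("A01" style), `role`
#' (`sample`, `neg_control`, `pos_control`, `empty`), `gene_id`, `sirna_id`,
#' `intensity`, `cell_count`, `dead_fraction`. Well labels are parsed and
#' checked against 384-well geometry; measurements must be numeric,
#' intensities finite and non-negative, dead fractions in `[0, 1]`, and
#' sample wells must carry a gene id.
#'
#' @param path input file.
#' @return validated well data frame with added `row`/`col` columns, ready
#'   for [screen_call()].
#' @export
read_well_table <- function(path) {
  tab <- .read_delim(path)
  miss <- setdiff(.required_well_cols, names(tab))
  if (length(miss)) {
    stop("read_well_table: missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in c("intensity", "cell_count", "dead_fraction", "replicate")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad)) {
      stop("read_well_table: non-numeric '", col, "' at data row ", bad[1])
    }
    tab[[col]] <- v
  }
  rc <- parse_well_label(tab$well)
  tab$row <- rc$row
  tab$col <- rc$col
  if (any(!tab$role %in% c("sample", "neg_control", "pos_control", "empty"))) {
    stop("read_well_table: unknown role value(s)")
  }
  fin <- is.finite(tab$intensity)
  if (any(!fin)) stop("read_well_table: non-finite intensity at data row ",
                      which(!fin)[1])
  if (any(tab$intensity < 0)) stop("read_well_table: negative intensity")
  if (any(tab$dead_fraction < 0 | tab$dead_fraction > 1, na.rm = TRUE)) {
    stop("read_well_table: dead_fraction outside [0, 1]")
  }
  no_gene <- tab$role == "sample" & (is.na(tab$gene_id) | tab$gene_id == "")
  if (any(no_gene)) {
    stop("read_well_table: sample well without gene_id at data row ",
         which(no_gene)[1])
  }
  tab
}

#' Read a long-format deconvolution table
#'
#' Columns `gene_id`, `sirna_id`, `assay`, `set_id`, `percent_inhibition`.
#'
#' @param path input file.
#' @return validated data frame for [run_cascade()].
#' @export
read_deconv_table <- function(path) {
  tab <- .read_delim(path)
  need <- c("gene_id", "sirna_id", "assay", "set_id", "percent_inhibition")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("read_deconv_table: missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  tab$set_id <- as.integer(tab$set_id)
  if (any(!tab$set_id %in% 1:2)) stop("read_deconv_table: set_id must be 1 or 2")
  v <- suppressWarnings(as.numeric(tab$percent_inhibition))
  if (any(is.na(v) & !is.na(tab$percent_inhibition))) {
    stop("read_deconv_table: non-numeric percent_inhibition")
  }
  tab$percent_inhibition <- v
  tab
}

#' Read a sensorgram trace with its injection schedule
#'
#' The trace file is two-column delimited text (`time_s`, `response_RU`); the
#' schedule file has columns `conc`, `start`, `stop`.
#'
#' @param trace_path,schedule_path input files.
#' @param single_cycle logical (default TRUE).
#' @return a `sensorgram` object.
#' @export
read_sensorgram <- function(trace_path, schedule_path, single_cycle = TRUE) {
  tr <- .read_delim(trace_path)
  if (ncol(tr) < 2L) stop("read_sensorgram: trace needs two columns")
  sched <- .read_delim(schedule_path)
  if (!all(c("conc", "start", "stop") %in% names(sched))) {
    stop("read_sensorgram: schedule needs conc, start, stop columns")
  }
  tm <- as.numeric(tr[[1]])
  if (is.unsorted(tm, strictly = TRUE)) {
    stop("read_sensorgram: time must be strictly increasing")
  }
  structure(list(time = tm, response = as.numeric(tr[[2]]),
                 schedule = sched, single_cycle = single_cycle),
            class = "sensorgram")
}

#' Write a table as CSV with run metadata
#'
#' Prepends "#"-prefixed metadata lines carrying the seed and a hash of the
#' run configuration, so every output records its provenance; the package's
#' readers skip these lines.
#'
#' @param tab data frame.
#' @param path output file.
#' @param config optional list; hashed into the header.
#' @param seed optional seed to record.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(tab, path, config = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    h <- sum(utf8ToInt(paste(deparse(config), collapse = "")) *
               seq_along(utf8ToInt(paste(deparse(config), collapse = "")))) %%
      .Machine$integer.max
    writeLines(sprintf("# config_hash=%d", h), con)
  }
  if (!is.null(seed)) writeLines(sprintf("# seed=%d", as.integer(seed)), con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a machine-readable run summary
#'
#' Stage counts and parameters as JSON, one object per run.
#'
#' @param summary named vector or list of counts.
#' @param path output file.
#' @param config optional `run_config` to embed.
#' @param seed optional seed to embed.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(summary, path, config = NULL, seed = NULL) {
  obj <- list(summary = as.list(summary))
  if (!is.null(config)) obj$config <- unclass(config)
  if (!is.null(seed)) obj$seed <- as.integer(seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run configuration with study-default thresholds
#'
#' Central parameter block for the pipeline. Every threshold defaults to the
#' study value: robust-z hit threshold 2.5, Z' acceptance 0.2, well QC 100
#' cells / 20% death, DiI confirmation 50%, transferrin bound 30%, LDLR
#' dependence 2-fold, fusion criterion 2.5 s.d. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults.
#' @return named list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    z_threshold = 2.5, zprime_min = 0.2, min_cells = 100L, max_dead = 0.20,
    dil_threshold = 50, tf_threshold = 30, ldlr_fold = 2,
    tf_overlap = "one", huvec_last = TRUE,
    fusion_k_sd = 2.5, min_track = 10L, window_frames = 5, max_drift_px = 3,
    stability_offset_s = 5, seed = 1L, out_dir = "results")
  ov <- list(...)
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown)) {
    stop("run_config: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  structure(utils::modifyList(defaults, ov), class = "run_config")
}
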