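# Delimited-text readers/writers: comma-separated, header row, '.' decimal.
# Doubles are written with %.17g so writer -> reader round-trips are
# bit-identical.

fmtNum <- function(x) sprintf("%.17g", x)

writeNumericCSV <- function(m, path) {
  df <- as.data.frame(m)
  df[] <- lapply(df, function(col)
    if (is.numeric(col)) fmtNum(col) else as.character(col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write a cohort to a directory of delimited text files
#'
#' Emits `phenotypes.csv`, one square matrix file per subject under
#' `connectivity/` (filename = subject id), `structural.csv` (id + feature
#' columns), optional `timeseries/` files, and `ground_truth.json` for
#' synthetic cohorts — the same on-disk layout the readers consume, so
#' synthetic and real data flow through identical paths.
#'
#' @param cohort a [Cohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ph <- as.data.frame(phenotypes(cohort))
  writeNumericCSV(ph, file.path(dir, "phenotypes.csv"))
  fcd <- file.path(dir, "connectivity")
  dir.create(fcd, showWarnings = FALSE)
  for (id in names(fcMatrices(cohort)))
    writeNumericCSV(fcMatrices(cohort)[[id]], file.path(fcd, paste0(id, ".csv")))
  if (length(cohort@timeseries)) {
    tsd <- file.path(dir, "timeseries")
    dir.create(tsd, showWarnings = FALSE)
    for (id in names(cohort@timeseries))
      writeNumericCSV(cohort@timeseries[[id]], file.path(tsd, paste0(id, ".csv")))
  }
  st <- structMatrix(cohort)
  if (ncol(st))
    writeNumericCSV(cbind(data.frame(id = rownames(st)), as.data.frame(st)),
                    file.path(dir, "structural.csv"))
  gt <- groundTruth(cohort)
  if (length(gt))
    jsonlite::write_json(gt[c("planted_edge_ids", "planted_struct_ids")],
                         file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Read the phenotype table
#' @param path `phenotypes.csv` path.
#' @export
readPhenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(ph$id))
    stop("duplicate participant id(s): ",
         paste(unique(ph$id[duplicated(ph$id)]), collapse = ", "),
         call. = FALSE)
  ph
}

readMatrixCSV <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = TRUE))
  if (!is.numeric(m))
    stop("non-numeric cell in ", basename(path), call. = FALSE)
  dimnames(m) <- NULL
  m
}

#' Read per-subject connectivity matrices
#'
#' One square matrix file per subject, filename = subject id. Asymmetric
#' files are rejected.
#' @param dir directory of `<id>.csv` files.
#' @param ids subject ids to load (error names any id without a file).
#' @export
readConnectivity <- function(dir, ids) {
  paths <- file.path(dir, paste0(ids, ".csv"))
  missing <- ids[!file.exists(paths)]
  if (length(missing))
    stop("missing connectivity matrix for id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- lapply(seq_along(ids), function(k) {
    m <- readMatrixCSV(paths[k])
    if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
      stop("asymmetric matrix file for id ", ids[k], call. = FALSE)
    m
  })
  names(out) <- ids
  out
}

#' Read the structural feature table
#' @param path `structural.csv` (first column `id`).
#' @param ids subject ids that must all be present.
#' @export
readStructural <- function(path, ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cell in structural table", call. = FALSE)
  rownames(m) <- df$id
  if (!is.null(ids)) {
    missing <- setdiff(ids, df$id)
    if (length(missing))
      stop("missing structural row for id(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    m <- m[ids, , drop = FALSE]
  }
  m
}

#' Read a cohort directory written by [writeCohort()]
#'
#' Row order follows the phenotype file; every id must be resolvable in
#' all sources.
#' @param dir cohort directory.
#' @export
readCohort <- function(dir) {
  ph <- readPhenotypes(file.path(dir, "phenotypes.csv"))
  fcd <- file.path(dir, "connectivity")
  fc <- if (dir.exists(fcd)) readConnectivity(fcd, ph$id) else list()
  tsd <- file.path(dir, "timeseries")
  ts <- if (dir.exists(tsd)) readConnectivityLike(tsd, ph$id) else list()
  stp <- file.path(dir, "structural.csv")
  st <- if (file.exists(stp)) readStructural(stp, ph$id)
        else matrix(numeric(0), nrow = 0L, ncol = 0L)
  gtp <- file.path(dir, "ground_truth.json")
  gt <- if (file.exists(gtp)) {
    g <- jsonlite::read_json(gtp, simplifyVector = TRUE)
    list(planted_edge_ids = as.integer(g$planted_edge_ids),
         planted_struct_ids = as.integer(g$planted_struct_ids))
  } else list()
  methods::new("Cohort", pheno = S4Vectors::DataFrame(ph), fc = fc,
               timeseries = ts, struct = st, groundTruth = gt)
}

readConnectivityLike <- function(dir, ids) {
  paths <- file.path(dir, paste0(ids, ".csv"))
  missing <- ids[!file.exists(paths)]
  if (length(missing))
    stop("missing time-series file for id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- lapply(paths, readMatrixCSV)
  names(out) <- ids
  out
}

#' Export a metrics report as JSON and a wide TSV
#'
#' The TSV has one row per architecture and validation/test/AUC columns
#' per ensemble mode, the shape used for cross-model comparison tables.
#'
#' @param results named list: for each architecture, a list with elements
#'   `cv` ([CVResult-class]) and optionally `nested`
#'   ([NestedCVResult-class]).
#' @param path_json,path_tsv output paths (either may be `NULL`).
#' @param meta optional metadata list embedded in the JSON (seeds, config
#'   hash).
#' @return the report data.frame, invisibly.
#' @export
writeMetricsReport <- function(results, path_json = NULL, path_tsv = NULL,
                               meta = list()) {
  rows <- lapply(names(results), function(arch) {
    r <- results[[arch]]
    out <- data.frame(architecture = arch,
                      validation = mean(r$cv@perFold$val_accuracy),
                      test = r$cv@accuracy, auc = r$cv@auc)
    if (!is.null(r$nested)) {
      out$test_max_voting <- r$nested@accuracy
      out$auc_max_voting <- r$nested@auc
    }
    out
  })
  tab <- do.call(rbind, rows)
  if (!is.null(path_json))
    jsonlite::write_json(c(meta, list(metrics = tab)), path_json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path_tsv))
    utils::write.table(tab, path_tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(tab)
}

#' Export a population graph as a three-column edge list
#'
#' Writes the upper-triangle edges (i, j, weight) as TSV; zero-weight
#' edges are dropped unless `keep_zeros`.
#' @param w symmetric weight matrix.
#' @param path output TSV path.
#' @param keep_zeros also write zero-weight pairs.
#' @export
writeEdgeList <- function(w, path, keep_zeros = FALSE) {
  stopifnot2(isSymmetricTol(w, 1e-8), "graph weights must be symmetric")
  ei <- edgeIndex(nrow(w))
  wt <- w[cbind(ei$i, ei$j)]
  keep <- if (keep_zeros) rep(TRUE, length(wt)) else wt != 0
  utils::write.table(data.frame(i = ei$i[keep], j = ei$j[keep],
                                weight = fmtNum(wt[keep])),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export an RFE selection as TSV (feature_id, rank, selected)
#' @param ranking a `SelectionRanking` from [rfeRank()].
#' @param k selection size passed to [selectTopK()].
#' @param path output TSV path.
#' @export
writeSelection <- function(ranking, k, path) {
  mask <- selectTopK(ranking, k)
  utils::write.table(data.frame(feature_id = names(ranking$rank),
                                rank = unname(ranking$rank),
                                selected = unname(mask)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a trained network to JSON (weights + spec + seed)
#' @param model a `NetClassifier`.
#' @param path output JSON path.
#' @export
writeClassifier <- function(model, path) {
  stopifnot2(methods::is(model, "NetClassifier"),
             "only network classifiers serialize to JSON")
  jsonlite::write_json(list(
    architecture = model@architecture, seed = model@seed,
    spec = model@spec[!vapply(model@spec, is.function, TRUE)],
    feature_ids = model@featureIds,
    selected_iteration = model@selectedIteration,
    params = model@params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
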