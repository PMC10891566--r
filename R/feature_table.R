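#' Construct a validated feature table
#'
#' A feature table is the central container of the package: a numeric matrix
#' of chromatographic peak areas with rows = samples and columns = compounds,
#' carrying aligned sample and compound metadata.  It mirrors the wide
#' sample-by-compound tables exported by untargeted LC-HRMS feature
#' extraction software after alignment and gap filling.
#'
#' @param areas numeric matrix `[n_samples x n_compounds]` of peak areas
#'   (arbitrary instrument units, all finite and non-negative).  Row and
#'   column names, if present, must agree with the metadata.
#' @param samples data.frame with columns `sample_id`, `site`, `site_type`
#'   (one of `"urban"`, `"industrial"`, `"blank"`), `dilution` (one of
#'   `"concentrated"`, `"diluted"`) and `replicate` (integer >= 1); one row
#'   per row of `areas`, in the same order.
#' @param compounds data.frame with columns `compound_id`, `mz` (Da, > 0),
#'   `rt` (minutes, >= 0), `name` (may be `NA`) and `confidence_level`
#'   (integer identification confidence, 1 = confirmed by standard ...
#'   5 = exact mass only); one row per column of `areas`.
#'
#' @return An object of class `feature_table`: a list with elements
#'   `areas`, `samples`, `compounds`.
#' @export
#' @examples
#' areas <- matrix(c(10, 20, 30, 40), 2, 2,
#'                 dimnames = list(c("U1c1", "U1c2"), c("C1", "C2")))
#' samples <- data.frame(sample_id = c("U1c1", "U1c2"), site = "U1",
#'                       site_type = "urban", dilution = "concentrated",
#'                       replicate = 1:2)
#' compounds <- data.frame(compound_id = c("C1", "C2"), mz = c(120.1, 255.2),
#'                         rt = c(2.5, 8.1), name = NA_character_,
#'                         confidence_level = 5L)
#' ft <- feature_table(areas, samples, compounds)
#' dim(ft$areas)
feature_table <- function(areas, samples, compounds) {
  if (!is.matrix(areas) || !is.numeric(areas)) {
    stop("'areas' must be a numeric matrix", call. = FALSE)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  compounds <- as.data.frame(compounds, stringsAsFactors = FALSE)
  if (nrow(compounds) == 0L) stop("no compounds", call. = FALSE)
  if (nrow(samples) == 0L) stop("no samples", call. = FALSE)
  need_s <- c("sample_id", "site", "site_type", "dilution", "replicate")
  miss <- setdiff(need_s, names(samples))
  if (length(miss)) {
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  need_c <- c("compound_id", "mz", "rt", "name", "confidence_level")
  miss <- setdiff(need_c, names(compounds))
  if (length(miss)) {
    stop("compound metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(areas) != nrow(samples)) {
    stop(sprintf("area matrix has %d rows but sample metadata has %d",
                 nrow(areas), nrow(samples)), call. = FALSE)
  }
  if (ncol(areas) != nrow(compounds)) {
    stop(sprintf("area matrix has %d columns but compound metadata has %d",
                 ncol(areas), nrow(compounds)), call. = FALSE)
  }
  if (anyNA(areas) || any(!is.finite(areas))) {
    bad <- which(!is.finite(areas), arr.ind = TRUE)[1L, , drop = TRUE]
    stop(sprintf(
      "non-finite peak area at row %d (sample '%s'), column %d (compound '%s')",
      bad[["row"]], samples$sample_id[bad[["row"]]],
      bad[["col"]], compounds$compound_id[bad[["col"]]]), call. = FALSE)
  }
  if (any(areas < 0)) {
    bad <- which(areas < 0, arr.ind = TRUE)[1L, , drop = TRUE]
    stop(sprintf(
      "negative peak area at row %d (sample '%s'), column %d (compound '%s')",
      bad[["row"]], samples$sample_id[bad[["row"]]],
      bad[["col"]], compounds$compound_id[bad[["col"]]]), call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(compounds$compound_id)) {
    stop("duplicated compound_id: ",
         paste(unique(compounds$compound_id[duplicated(compounds$compound_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (!is.null(rownames(areas)) && !identical(rownames(areas),
                                              as.character(samples$sample_id))) {
    off <- rownames(areas)[rownames(areas) != samples$sample_id]
    stop("area matrix row names do not match sample metadata; offenders: ",
         paste(utils::head(off, 5L), collapse = ", "), call. = FALSE)
  }
  if (!is.null(colnames(areas)) && !identical(colnames(areas),
                                              as.character(compounds$compound_id))) {
    off <- colnames(areas)[colnames(areas) != compounds$compound_id]
    stop("area matrix column names do not match compound metadata; offenders: ",
         paste(utils::head(off, 5L), collapse = ", "), call. = FALSE)
  }
  bad_type <- setdiff(unique(samples$site_type),
                      c("urban", "industrial", "blank"))
  if (length(bad_type)) {
    stop("unknown site_type: ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  bad_dil <- setdiff(unique(samples$dilution), c("concentrated", "diluted"))
  if (length(bad_dil)) {
    stop("unknown dilution level: ", paste(bad_dil, collapse = ", "),
         call. = FALSE)
  }
  if (any(samples$replicate < 1)) stop("replicate must be >= 1", call. = FALSE)
  if (any(compounds$mz <= 0)) stop("mz must be > 0", call. = FALSE)
  if (any(compounds$rt < 0)) stop("rt must be >= 0", call. = FALSE)
  if (!all(compounds$confidence_level %in% 1:5)) {
    stop("confidence_level must be an integer in 1..5", call. = FALSE)
  }
  dimnames(areas) <- list(as.character(samples$sample_id),
                          as.character(compounds$compound_id))
  structure(list(areas = areas, samples = samples, compounds = compounds),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d compounds\n",
              nrow(x$areas), ncol(x$areas)))
  tab <- table(x$samples$site_type)
  cat("  samples:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  areas: [%.3g, %.3g]\n", min(x$areas), max(x$areas)))
  invisible(x)
}

#' Subset a feature table
#'
#' Selects samples (rows) and/or compounds (columns), keeping metadata
#' aligned.  Indices may be logical, integer or character (ids).
#'
#' @param table a [feature_table()].
#' @param samples,compounds row / column selector; `NULL` keeps all.
#' @return a `feature_table`.
#' @export
ft_subset <- function(table, samples = NULL, compounds = NULL) {
  stopifnot(inherits(table, "feature_table"))
  si <- if (is.null(samples)) seq_len(nrow(table$areas)) else samples
  ci <- if (is.null(compounds)) seq_len(ncol(table$areas)) else compounds
  if (is.character(si)) si <- match(si, table$samples$sample_id)
  if (is.character(ci)) ci <- match(ci, table$compounds$compound_id)
  if (anyNA(si)) stop("unknown sample id in selector", call. = FALSE)
  if (anyNA(ci)) stop("unknown compound id in selector", call. = FALSE)
  # subsetting a valid table cannot invalidate it, so construct directly
  # (also keeps z-scored tables and empty subsets representable)
  out <- list(areas = table$areas[si, ci, drop = FALSE],
              samples = table$samples[si, , drop = FALSE],
              compounds = table$compounds[ci, , drop = FALSE])
  class(out) <- class(table)
  out
}

#' Build a sample identifier from its components
#'
#' Sample names follow the convention used in the analysis sequence:
#' site, then a dilution letter (`c` concentrated, `d` diluted, `b` blank),
#' then the replicate number; e.g. the first concentrated replicate at
#' urban site U1 is `"U1c1"`.
#'
#' @param site site label, e.g. `"U1"` or `"I3"`.
#' @param dilution `"concentrated"`, `"diluted"` or `"blank"`.
#' @param replicate integer >= 1.
#' @return character sample id.
#' @export
#' @examples
#' sample_name_build("U1", "concentrated", 1)  # "U1c1"
sample_name_build <- function(site, dilution, replicate) {
  code <- c(concentrated = "c", diluted = "d", blank = "b")[dilution]
  if (anyNA(code)) stop("unknown dilution level: ", dilution, call. = FALSE)
  paste0(site, code, as.integer(replicate))
}

#' Parse a sample identifier into its components
#'
#' Inverse of [sample_name_build()].
#'
#' @param sample_id character vector of ids such as `"U1c1"`, `"I3d2"`.
#' @return data.frame with columns `sample_id`, `site`, `dilution`,
#'   `replicate`.
#' @export
sample_name_parse <- function(sample_id) {
  m <- regmatches(sample_id,
                  regexec("^(.*?)([cdb])([0-9]+)$", sample_id))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("unparseable sample id: ",
         paste(sample_id[bad], collapse = ", "), call. = FALSE)
  }
  site <- vapply(m, `[`, "", 2L)
  code <- vapply(m, `[`, "", 3L)
  data.frame(
    sample_id = sample_id,
    site = site,
    dilution = c(c = "concentrated", d = "diluted", b = "blank")[code],
    replicate = as.integer(vapply(m, `[`, "", 4L)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a feature table from the three-file CSV layout
#'
#' Expects `areas.csv` (first column `sample_id`, remaining columns one per
#' compound), `samples.csv` (`sample_id,site,site_type,dilution,replicate`)
#' and `compounds.csv` (`compound_id,mz,rt,name,confidence_level`), all
#' RFC-4180-style comma-separated UTF-8 with a header row.  Row/column
#' order is preserved from file; ids must agree across files.
#'
#' @param areas_path,samples_path,compounds_path CSV file paths.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(areas_path, samples_path, compounds_path) {
  for (p in c(areas_path, samples_path, compounds_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  araw <- utils::read.csv(areas_path, check.names = FALSE,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  samples <- utils::read.csv(samples_path, stringsAsFactors = FALSE,
                             encoding = "UTF-8")
  compounds <- utils::read.csv(compounds_path, stringsAsFactors = FALSE,
                               encoding = "UTF-8",
                               colClasses = c(name = "character"))
  if (names(araw)[1L] != "sample_id") {
    stop("areas.csv must have 'sample_id' as its first column",
         call. = FALSE)
  }
  if (nrow(compounds) == 0L || ncol(araw) < 2L) {
    stop("no compounds", call. = FALSE)
  }
  areas <- as.matrix(araw[, -1L, drop = FALSE])
  storage.mode(areas) <- "double"
  rownames(areas) <- araw$sample_id
  mism <- setdiff(
    union(araw$sample_id, samples$sample_id),
    intersect(araw$sample_id, samples$sample_id))
  if (length(mism)) {
    stop("sample ids disagree between areas and metadata: ",
         paste(mism, collapse = ", "), call. = FALSE)
  }
  mism <- setdiff(
    union(colnames(areas), compounds$compound_id),
    intersect(colnames(areas), compounds$compound_id))
  if (length(mism)) {
    stop("compound ids disagree between areas and metadata: ",
         paste(mism, collapse = ", "), call. = FALSE)
  }
  compounds$name[is.na(compounds$name)] <- NA_character_
  feature_table(areas, samples, compounds)
}

#' Write a feature table to the three-file CSV layout
#'
#' Emits `areas.csv`, `samples.csv` and `compounds.csv` under `out_dir`
#' with fixed column order, so that [read_feature_table()] on the output
#' reproduces the table exactly.
#'
#' @param table a [feature_table()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a named character vector of the three file paths.
#' @export
write_feature_table <- function(table, out_dir) {
  stopifnot(inherits(table, "feature_table"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(areas = file.path(out_dir, "areas.csv"),
             samples = file.path(out_dir, "samples.csv"),
             compounds = file.path(out_dir, "compounds.csv"))
  adf <- data.frame(sample_id = table$samples$sample_id,
                    table$areas, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(adf, paths[["areas"]], row.names = FALSE,
                   fileEncoding = "UTF-8")
  utils::write.csv(
    table$samples[, c("sample_id", "site", "site_type", "dilution",
                      "replicate")],
    paths[["samples"]], row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(
    table$compounds[, c("compound_id", "mz", "rt", "name",
                        "confidence_level")],
    paths[["compounds"]], row.names = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}

#' Serialize a fitted model to JSON
#'
#' Supports [zscore_fit()] scaling models, [som_train()] SOM models and
#' [pca_fit()] PCA models.  The document carries a `schema` tag and a
#' `version` field; all numeric fields are written at full precision so
#' that [deserialize_model()] round-trips exactly.
#'
#' @param model a `scaling_model`, `som_model` or `pca_model`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
serialize_model <- function(model, path) {
  schema <- if (inherits(model, "scaling_model")) "scaling_model"
  else if (inherits(model, "som_model")) "som_model"
  else if (inherits(model, "pca_model")) "pca_model"
  else stop("unknown model kind: ", paste(class(model), collapse = "/"),
            call. = FALSE)
  doc <- list(schema = schema, version = 1L, payload = unclass_deep(model))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

# strip S3 classes recursively; matrices become row-major lists with
# dims, named atomic vectors keep their names alongside the data
unclass_deep <- function(x) {
  if (is.matrix(x)) {
    list(.matrix = TRUE, dim = dim(x), dimnames = dimnames(x),
         data = as.vector(t(x)))
  } else if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else if (is.atomic(x) && !is.null(names(x))) {
    list(.named = TRUE, names = names(x), data = unname(x))
  } else {
    x
  }
}

reclass_deep <- function(x) {
  if (is.list(x) && isTRUE(x$.matrix)) {
    m <- matrix(unlist(x$data), nrow = x$dim[[1L]], byrow = TRUE)
    if (!is.null(x$dimnames)) {
      dimnames(m) <- lapply(x$dimnames, function(d) unlist(d))
    }
    m
  } else if (is.list(x) && isTRUE(x$.named)) {
    stats::setNames(unlist(x$data), unlist(x$names))
  } else if (is.list(x)) {
    lapply(x, reclass_deep)
  } else {
    x
  }
}

#' Load a model written by [serialize_model()]
#'
#' @param path JSON file path.
#' @return the model, with its class restored.
#' @export
deserialize_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE,
                             simplifyDataFrame = FALSE)
  if (is.null(doc$schema) || is.null(doc$version)) {
    stop("not a model file (missing schema/version): ", path, call. = FALSE)
  }
  payload <- reclass_deep(doc$payload)
  restore_model(payload, doc$schema)
}

restore_model <- function(payload, schema) {
  switch(schema,
    scaling_model = {
      payload$means <- unlist(payload$means)
      payload$sds <- unlist(payload$sds)
      payload$fitted_on <- as.character(unlist(payload$fitted_on))
      payload$dropped <- as.character(unlist(payload$dropped))
      structure(payload, class = "scaling_model")
    },
    som_model = {
      payload$grid <- restore_grid(payload$grid)
      payload$hit_counts <- unlist(payload$hit_counts)
      if (!is.null(payload$scaling)) {
        payload$scaling <- restore_model(payload$scaling, "scaling_model")
      }
      structure(payload, class = "som_model")
    },
    pca_model = {
      payload$eigenvalues <- unlist(payload$eigenvalues)
      payload$center_scores <- unlist(payload$center_scores)
      if (!is.null(payload$scaling)) {
        payload$scaling <- restore_model(payload$scaling, "scaling_model")
      }
      structure(payload, class = "pca_model")
    },
    stop("unknown model schema: ", schema, call. = FALSE))
}

restore_grid <- function(g) {
  g$xdim <- as.integer(g$xdim)
  g$ydim <- as.integer(g$ydim)
  structure(g, class = "som_grid")
}
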