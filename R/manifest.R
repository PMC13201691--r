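#' The 14-class chest-radiograph finding vocabulary
#'
#' NIH ChestX-ray14 finding names plus the `"No Finding"` sentinel that marks
#' a normal radiograph. `"No Finding"` is never a positive label: a record
#' carrying it must carry nothing else.
#'
#' @param include_sentinel include the `"No Finding"` sentinel (default TRUE)
#' @return character vector of class names
#' @export
cxr14_vocabulary <- function(include_sentinel = TRUE) {
  v <- c("Atelectasis", "Cardiomegaly", "Effusion", "Infiltration", "Mass",
         "Nodule", "Pneumonia", "Pneumothorax", "Consolidation", "Edema",
         "Emphysema", "Fibrosis", "Pleural Thickening", "Hernia")
  if (include_sentinel) c(v, "No Finding") else v
}

sentinel <- "No Finding"

#' Read an image label manifest
#'
#' Reads a CSV manifest in the NIH ChestX-ray14 dialect: an image-filename
#' column and a pipe-delimited findings column (e.g.
#' `"Effusion|Cardiomegaly"`). A CheXpert-style dialect with one 0/1/-1
#' column per class is also accepted (`dialect = "per_class"`; uncertain
#' labels, -1, map to 0).
#'
#' @param csv_path path to the CSV file
#' @param image_dir optional directory holding the images; when given, every
#'   image file must exist
#' @param vocabulary ordered class vocabulary including the `"No Finding"`
#'   sentinel
#' @param dialect `"nih"` (filename + pipe-delimited findings) or
#'   `"per_class"`
#' @return an object of class `cxr_manifest`: a list with `records` (tibble
#'   of `image_id` and a `labels` list-column), `vocabulary` (positive
#'   classes, sentinel excluded) and `image_dir`
#' @export
read_manifest <- function(csv_path, image_dir = NULL,
                          vocabulary = cxr14_vocabulary(),
                          dialect = c("nih", "per_class")) {
  dialect <- match.arg(dialect)
  if (!file.exists(csv_path)) stop("manifest not found: ", csv_path,
                                   call. = FALSE)
  df <- read.csv(csv_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "nih") {
    if (ncol(df) < 2L) stop("NIH-dialect manifest needs a filename column ",
                            "and a findings column", call. = FALSE)
    ids <- as.character(df[[1L]])
    findings <- strsplit(as.character(df[[2L]]), "|", fixed = TRUE)
  } else {
    ids <- as.character(df[[1L]])
    classes <- intersect(colnames(df), setdiff(vocabulary, sentinel))
    if (length(classes) == 0L) stop("per-class manifest has no recognised ",
                                    "class columns", call. = FALSE)
    findings <- lapply(seq_len(nrow(df)), function(i) {
      pos <- classes[vapply(classes, function(cl) {
        x <- suppressWarnings(as.numeric(df[[cl]][i]))
        !is.na(x) && x == 1          # uncertain (-1) and blank map to 0
      }, logical(1L))]
      if (length(pos) == 0L) sentinel else pos
    })
  }
  new_manifest(ids, findings, vocabulary, image_dir, check_files = TRUE)
}

new_manifest <- function(ids, findings, vocabulary, image_dir,
                         check_files = FALSE) {
  findings <- lapply(findings, function(f) {
    f <- trimws(f)
    f[!is.na(f)]
  })
  bad_empty <- which(vapply(findings, function(f) {
    length(f) == 0L || all(f == "")
  }, logical(1L)))
  if (length(bad_empty) > 0L) {
    stop("empty findings field at row(s) ",
         paste(utils::head(bad_empty, 5L), collapse = ", "), call. = FALSE)
  }
  unknown <- lapply(findings, function(f) setdiff(f, vocabulary))
  bad_unknown <- which(vapply(unknown, length, integer(1L)) > 0L)
  if (length(bad_unknown) > 0L) {
    stop("unknown class name(s) ",
         paste(unique(unlist(unknown)), collapse = ", "),
         " at row(s) ", paste(utils::head(bad_unknown, 5L), collapse = ", "),
         call. = FALSE)
  }
  bad_sentinel <- which(vapply(findings, function(f) {
    sentinel %in% f && length(f) > 1L
  }, logical(1L)))
  if (length(bad_sentinel) > 0L) {
    stop("'", sentinel, "' co-occurs with other findings at row(s) ",
         paste(utils::head(bad_sentinel, 5L), collapse = ", "), call. = FALSE)
  }
  if (check_files && !is.null(image_dir)) {
    paths <- file.path(image_dir, ids)
    missing <- which(!file.exists(paths))
    if (length(missing) > 0L) {
      stop("image file(s) missing under ", image_dir, ": ",
           paste(utils::head(ids[missing], 5L), collapse = ", "),
           " (row(s) ", paste(utils::head(missing, 5L), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  positives <- lapply(findings, function(f) setdiff(f, sentinel))
  structure(list(
    records = tibble::tibble(image_id = ids, labels = positives),
    vocabulary = setdiff(vocabulary, sentinel),
    image_dir = image_dir
  ), class = "cxr_manifest")
}

#' Write a manifest in the NIH CSV dialect
#'
#' @param manifest a `cxr_manifest`
#' @param csv_path output path
#' @return `csv_path`, invisibly
#' @export
write_manifest <- function(manifest, csv_path) {
  findings <- vapply(manifest$records$labels, function(f) {
    if (length(f) == 0L) sentinel else paste(f, collapse = "|")
  }, character(1L))
  df <- data.frame(`Image Index` = manifest$records$image_id,
                   `Finding Labels` = findings, check.names = FALSE)
  write.csv(df, csv_path, row.names = FALSE)
  invisible(csv_path)
}

#' Binary label matrix view of a manifest
#'
#' @param manifest a `cxr_manifest`
#' @return integer matrix `n x L` in vocabulary order (sentinel excluded);
#'   rows named by image id
#' @export
label_matrix <- function(manifest) {
  v <- manifest$vocabulary
  m <- do.call(rbind, lapply(manifest$records$labels,
                             function(f) as.integer(v %in% f)))
  dimnames(m) <- list(manifest$records$image_id, v)
  m
}

#' @export
print.cxr_manifest <- function(x, ...) {
  cat("cxr_manifest: ", nrow(x$records), " images, ",
      length(x$vocabulary), " classes",
      if (!is.null(x$image_dir)) paste0(", dir ", x$image_dir), "\n",
      sep = "")
  pos <- colSums(label_matrix(x))
  cat("  positives per class: ", paste(pos, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Collapse a multi-label manifest to the binary normal/abnormal task
#'
#' A record is normal (label 0) iff its positive set is empty, i.e. it was
#' labelled exactly `"No Finding"`; every other record is abnormal (1).
#'
#' @param manifest a `cxr_manifest`
#' @return a `cxr_manifest` with a single `"Abnormal"` class
#' @export
binarize_labels <- function(manifest) {
  findings <- lapply(manifest$records$labels, function(f) {
    if (length(f) == 0L) sentinel else "Abnormal"
  })
  new_manifest(manifest$records$image_id, findings,
               c("Abnormal", sentinel), manifest$image_dir)
}

#' Random train/test split of a manifest
#'
#' Image-level split by default, reproducible given the seed; the train set
#' gets `floor(n * train_fraction)` images. A patient-level split keeps all
#' images of one patient on the same side and requires a `patient_id`
#' column in `records`.
#'
#' @param manifest a `cxr_manifest`
#' @param train_fraction fraction in (0, 1), default 0.8
#' @param seed RNG seed
#' @param by `"image"` (default) or `"patient"`
#' @return list of two manifests, `train` and `test`
#' @export
split_dataset <- function(manifest, train_fraction = 0.8, seed = 1L,
                          by = c("image", "patient")) {
  by <- match.arg(by)
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(manifest$records)
  if (n < 2L) stop("cannot split a manifest with fewer than 2 images",
                   call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (by == "image") {
    idx <- sample.int(n)
    k <- floor(n * train_fraction)
    tr <- sort(idx[seq_len(k)])
    te <- sort(idx[-seq_len(k)])
  } else {
    pid <- manifest$records$patient_id
    if (is.null(pid)) stop("patient-level split needs a patient_id column",
                           call. = FALSE)
    up <- sample(unique(pid))
    k <- floor(length(up) * train_fraction)
    tr <- which(pid %in% up[seq_len(k)])
    te <- which(!(pid %in% up[seq_len(k)]))
  }
  list(train = subset_manifest(manifest, tr),
       test = subset_manifest(manifest, te))
}

subset_manifest <- function(manifest, idx) {
  out <- manifest
  out$records <- manifest$records[idx, , drop = FALSE]
  out
}
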