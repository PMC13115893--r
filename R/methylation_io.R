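# Beta-matrix and annotation containers plus harmonization.
#
# A beta matrix is CpG x sample with values on the bounded [0,1] beta scale;
# the sample sheet carries the class label (1 = OA, 0 = control), the batch
# (source dataset) and optionally the joint site.

#' Construct a validated beta-value matrix
#'
#' @param values Numeric matrix, CpGs in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids). Finite values must lie in
#'   \[0,1\]; `NA` is allowed (removed during harmonization).
#' @param labels Integer vector (0 = control, 1 = case), one per sample.
#' @param batch Character vector of batch/dataset identifiers, one per
#'   sample.
#' @param joint Optional character vector of joint-site labels (e.g. knee,
#'   hip).
#' @return An object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, labels, batch, joint = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_oam("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_oam("'values' must carry probe rownames and sample colnames")
  }
  if (nrow(values) == 0 || ncol(values) == 0) {
    stop_oam("empty beta matrix")
  }
  if (anyDuplicated(rownames(values))) {
    stop_oam("duplicate probe id: %s",
             rownames(values)[duplicated(rownames(values))][1])
  }
  if (anyDuplicated(colnames(values))) {
    stop_oam("duplicate sample id: %s",
             colnames(values)[duplicated(colnames(values))][1])
  }
  check_beta_range(values)
  labels <- as.integer(labels)
  if (length(labels) != ncol(values) || !all(labels %in% c(0L, 1L))) {
    stop_oam("'labels' must be 0/1, one per sample")
  }
  batch <- as.character(batch)
  if (length(batch) != ncol(values)) {
    stop_oam("'batch' must have one entry per sample")
  }
  if (!is.null(joint)) {
    joint <- as.character(joint)
    if (length(joint) != ncol(values)) {
      stop_oam("'joint' must have one entry per sample")
    }
  }
  structure(
    list(values = values, cpg_ids = rownames(values),
         sample_ids = colnames(values), labels = labels, batch = batch,
         joint = joint),
    class = "beta_matrix"
  )
}

check_beta_range <- function(values) {
  bad <- which(is.finite(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_oam("beta value %g outside [0,1] at probe %s, sample %s",
             values[bad[1, 1], bad[1, 2]],
             rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]])
  }
  inf <- which(!is.na(values) & !is.finite(values), arr.ind = TRUE)
  if (nrow(inf) > 0) {
    stop_oam("non-finite beta value at probe %s, sample %s",
             rownames(values)[inf[1, 1]], colnames(values)[inf[1, 2]])
  }
  invisible(TRUE)
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("beta_matrix: %d CpGs x %d samples (%d case / %d control; %d batches)\n",
              nrow(x$values), ncol(x$values), sum(x$labels == 1L),
              sum(x$labels == 0L), length(unique(x$batch))))
  invisible(x)
}

#' Construct a CpG annotation object
#'
#' @param probes data.frame with columns `cpg_id`, `chrom`, `pos`
#'   (1-based coordinate).
#' @param links data.frame with columns `cpg_id`, `gene`, `tss`
#'   (1-based TSS coordinate), `strand`; zero rows allowed.
#' @return An object of class `cpg_annotation`.
#' @export
cpg_annotation <- function(probes, links) {
  need_p <- c("cpg_id", "chrom", "pos")
  need_l <- c("cpg_id", "gene", "tss", "strand")
  if (!all(need_p %in% names(probes))) {
    stop_oam("'probes' must have columns %s", paste(need_p, collapse = ", "))
  }
  if (!all(need_l %in% names(links))) {
    stop_oam("'links' must have columns %s", paste(need_l, collapse = ", "))
  }
  if (anyDuplicated(probes$cpg_id)) stop_oam("duplicate cpg_id in annotation")
  if (nrow(probes) > 0 && any(probes$pos < 1)) stop_oam("positions must be >= 1")
  if (nrow(links) > 0 && !all(links$cpg_id %in% probes$cpg_id)) {
    stop_oam("links reference probes absent from the probe table")
  }
  structure(list(probes = probes, links = links), class = "cpg_annotation")
}

#' @export
print.cpg_annotation <- function(x, ...) {
  cat(sprintf("cpg_annotation: %d probes, %d gene links (%d genes)\n",
              nrow(x$probes), nrow(x$links), length(unique(x$links$gene))))
  invisible(x)
}

#' Read a beta matrix and its sample sheet from TSV files
#'
#' The matrix file is tab-separated with the probe id in the first column
#' and one column per sample; the sample sheet is tab-separated with
#' columns `sample_id`, `label`, `batch` and optionally `joint`. Every
#' matrix sample must appear in the sheet.
#'
#' @param matrix_path Path to the beta-value TSV.
#' @param sample_sheet_path Path to the sample-sheet TSV.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(matrix_path, sample_sheet_path) {
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop_oam("matrix file must have probe id + sample columns")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stop_oam("duplicate probe id: %s", ids[duplicated(ids)][1])
  }
  values <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(values)) stop_oam("non-numeric beta values in %s", matrix_path)
  rownames(values) <- ids

  sheet <- utils::read.delim(sample_sheet_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "label", "batch")
  if (!all(need %in% names(sheet))) {
    stop_oam("sample sheet must have columns %s", paste(need, collapse = ", "))
  }
  missing <- setdiff(colnames(values), sheet$sample_id)
  if (length(missing) > 0) {
    stop_oam("samples missing from sample sheet: %s",
             paste(missing, collapse = ", "))
  }
  sheet <- sheet[match(colnames(values), sheet$sample_id), , drop = FALSE]
  beta_matrix(values, labels = sheet$label, batch = sheet$batch,
              joint = if ("joint" %in% names(sheet)) sheet$joint else NULL)
}

#' Write a beta matrix (and sample sheet) to TSV files
#'
#' Values are written at the given decimal precision so that
#' `read_beta_matrix()` round-trips the file bit-identically.
#'
#' @param matrix A [beta_matrix()].
#' @param out_path Output path for the beta-value TSV.
#' @param sheet_path Output path for the sample sheet; default
#'   `paste0(out_path, ".sheet.tsv")`.
#' @param precision Decimal places written.
#' @return `out_path`, invisibly.
#' @export
write_beta_matrix <- function(matrix, out_path,
                              sheet_path = paste0(out_path, ".sheet.tsv"),
                              precision = 4L) {
  stopifnot(inherits(matrix, "beta_matrix"))
  vals <- round(matrix$values, precision)
  df <- data.frame(cpg_id = matrix$cpg_ids,
                   format(vals, trim = TRUE, nsmall = 0, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("cpg_id", matrix$sample_ids)
  utils::write.table(df, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- data.frame(sample_id = matrix$sample_ids, label = matrix$labels,
                      batch = matrix$batch,
                      joint = if (is.null(matrix$joint)) NA else matrix$joint,
                      stringsAsFactors = FALSE)
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out_path)
}

#' Read a CpG annotation from a 450K-manifest-like CSV
#'
#' Expected columns: `IlmnID`, `CHR`, `MAPINFO`, `UCSC_RefGene_Name`
#' (semicolon-separated gene symbols), `TSS` (semicolon-separated 1-based
#' TSS coordinates, matched positionally to the gene symbols) and
#' optionally `Strand` (semicolon-separated).
#'
#' @param path CSV file path.
#' @return A [cpg_annotation()].
#' @export
read_cpg_annotation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("IlmnID", "CHR", "MAPINFO", "UCSC_RefGene_Name", "TSS")
  if (!all(need %in% names(df))) {
    stop_oam("annotation CSV must have columns %s", paste(need, collapse = ", "))
  }
  probes <- data.frame(cpg_id = df$IlmnID, chrom = as.character(df$CHR),
                       pos = as.integer(df$MAPINFO), stringsAsFactors = FALSE)
  has_strand <- "Strand" %in% names(df)
  links <- lapply(seq_len(nrow(df)), function(i) {
    g <- df$UCSC_RefGene_Name[i]
    if (is.na(g) || !nzchar(g)) return(NULL)
    genes <- strsplit(g, ";", fixed = TRUE)[[1]]
    tss <- as.integer(strsplit(as.character(df$TSS[i]), ";", fixed = TRUE)[[1]])
    if (length(tss) != length(genes)) {
      stop_oam("probe %s: gene/TSS count mismatch", df$IlmnID[i])
    }
    strand <- if (has_strand) {
      strsplit(as.character(df$Strand[i]), ";", fixed = TRUE)[[1]]
    } else rep("+", length(genes))
    data.frame(cpg_id = df$IlmnID[i], gene = genes, tss = tss,
               strand = rep_len(strand, length(genes)),
               stringsAsFactors = FALSE)
  })
  links <- do.call(rbind, links[!vapply(links, is.null, logical(1))])
  if (is.null(links)) {
    links <- data.frame(cpg_id = character(0), gene = character(0),
                        tss = integer(0), strand = character(0))
  }
  cpg_annotation(probes, links)
}

#' Write a CpG annotation to a 450K-manifest-like CSV
#'
#' @param annotation A [cpg_annotation()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cpg_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "cpg_annotation"))
  pr <- annotation$probes
  ln <- annotation$links
  agg <- function(col) {
    v <- vapply(pr$cpg_id, function(id) {
      paste(ln[[col]][ln$cpg_id == id], collapse = ";")
    }, character(1))
    v
  }
  out <- data.frame(IlmnID = pr$cpg_id, CHR = pr$chrom, MAPINFO = pr$pos,
                    UCSC_RefGene_Name = agg("gene"), TSS = agg("tss"),
                    Strand = agg("strand"), stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Harmonize one or more beta-matrix datasets
#'
#' Applies the standard preprocessing contract: keep only CpGs common to
#' all datasets, drop CpGs with any missing value, correct batch effects by
#' per-(batch, probe) mean-centering re-anchored to the probe's global mean
#' (then clipped to \[0,1\]), standardize numerical precision by rounding
#' (half-to-even) to `precision` decimals, and order probes genomically by
#' (chromosome, position, probe id).
#'
#' @param datasets A single [beta_matrix()] or a list of them; batches are
#'   taken from each matrix's `batch` field.
#' @param annotation A [cpg_annotation()] covering the retained probes.
#' @param precision Decimal places for precision standardization.
#' @param batch_correct Apply the batch location adjustment (default TRUE).
#' @return A harmonized [beta_matrix()].
#' @export
harmonize_datasets <- function(datasets, annotation, precision = 4L,
                               batch_correct = TRUE) {
  if (inherits(datasets, "beta_matrix")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, inherits, logical(1), "beta_matrix")),
            inherits(annotation, "cpg_annotation"))
  common <- Reduce(intersect, lapply(datasets, function(d) d$cpg_ids))
  if (length(common) == 0) stop_oam("no CpG sites common to all datasets")

  values <- do.call(cbind, lapply(datasets, function(d) d$values[common, , drop = FALSE]))
  labels <- unlist(lapply(datasets, function(d) d$labels), use.names = FALSE)
  batch <- unlist(lapply(datasets, function(d) d$batch), use.names = FALSE)
  joints <- lapply(datasets, function(d) d$joint)
  joint <- if (any(vapply(joints, is.null, logical(1)))) NULL else
    unlist(joints, use.names = FALSE)
  if (anyDuplicated(colnames(values))) {
    stop_oam("duplicate sample id across datasets: %s",
             colnames(values)[duplicated(colnames(values))][1])
  }

  keep <- rowSums(is.na(values)) == 0
  values <- values[keep, , drop = FALSE]
  if (nrow(values) == 0) stop_oam("no probes left after missing-value removal")

  if (batch_correct && length(unique(batch)) > 1) {
    # Centering then clipping can leave batch means unequal where clipping
    # bites; iterate to a fixed point so the adjustment is idempotent.
    for (iter in seq_len(50L)) {
      gm <- rowMeans(values)
      dev <- 0
      for (b in unique(batch)) {
        sel <- batch == b
        bm <- rowMeans(values[, sel, drop = FALSE])
        dev <- max(dev, max(abs(bm - gm)))
        values[, sel] <- values[, sel] - bm + gm
      }
      values <- pmin(pmax(values, 0), 1)
      if (dev < 1e-10) break
    }
  }
  values <- round(values, precision)

  ord <- genomic_order(rownames(values), annotation)
  values <- values[ord, , drop = FALSE]
  beta_matrix(values, labels = labels, batch = batch, joint = joint)
}

# Deterministic genomic total order: chr1..chr22, chrX, chrY, others
# lexicographic after; then position; then probe id.
genomic_order <- function(cpg_ids, annotation) {
  idx <- match(cpg_ids, annotation$probes$cpg_id)
  if (anyNA(idx)) {
    stop_oam("annotation does not cover probes: %s",
             paste(utils::head(cpg_ids[is.na(idx)], 5), collapse = ", "))
  }
  order(chrom_rank(annotation$probes$chrom[idx]),
        annotation$probes$pos[idx], cpg_ids)
}
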