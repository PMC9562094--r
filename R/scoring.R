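#' Default score-transform configuration
#'
#' Raw association statistics arrive on wildly different scales (p-values,
#' fold changes, LOD scores, network degrees, clustering coefficients,
#' literature reference counts, curated preset scores). Each is transformed
#' onto a common bounded 0-10 scale so that no single platform dominates a
#' gene's combined score. The transform families are log10 for p-values,
#' absolute log2 for fold change, floor for LOD, and step functions for the
#' count-like kinds; every result is capped at `cap`.
#'
#' Step functions are given as parallel `thresholds`/`scores` vectors: a
#' value scores `scores[i]` for the largest `i` with
#' `value >= thresholds[i]`, and 0 below the first threshold.
#'
#' @param cap upper bound for every emitted score (default 10).
#' @return list with `cap` and per-kind step-function definitions.
#' @export
default_score_caps <- function(cap = 10) {
  list(
    cap = cap,
    ref_count = list(thresholds = c(1, 2, 4), scores = c(1, 2, 3)),
    degree = list(thresholds = c(1, 5, 10, 20, 50), scores = c(1, 2, 3, 4, 5)),
    cluster_coefficient = list(thresholds = c(0, 0.25, 0.5, 0.75),
                               scores = c(1, 2, 3, 4))
  )
}

.step_lookup <- function(value, def) {
  idx <- findInterval(value, def$thresholds)
  out <- numeric(length(value))
  out[idx > 0] <- def$scores[idx[idx > 0]]
  out
}

#' Transform one kind of raw evidence value into a bounded score
#'
#' @param value numeric vector of raw statistics, all of the same kind.
#' @param value_kind one of `"pvalue"`, `"fold_change"`, `"lod"`,
#'   `"degree"`, `"cluster_coefficient"`, `"ref_count"`, `"preset_score"`.
#' @param is_log for `fold_change` only: `TRUE` when the value is already
#'   log2-scaled (it is then used as-is, absolute value).
#' @param caps configuration from [default_score_caps()].
#' @return numeric vector of scores in `[0, caps$cap]`.
#' @examples
#' evidence_to_score(0.001, "pvalue")       # 3
#' evidence_to_score(4, "fold_change")      # 2
#' evidence_to_score(3.7, "lod")            # 3
#' @export
evidence_to_score <- function(value, value_kind, is_log = FALSE,
                              caps = default_score_caps()) {
  value <- as.numeric(value)
  cap <- caps$cap
  s <- switch(value_kind,
    pvalue = {
      if (any(value <= 0 | value > 1))
        stop("invalid evidence: p-value outside (0, 1]")
      -log10(value)
    },
    fold_change = {
      if (is_log) abs(value)
      else {
        if (any(value <= 0)) stop("invalid evidence: fold change must be > 0")
        abs(log2(value))
      }
    },
    lod = {
      if (any(value < 0)) stop("invalid evidence: LOD must be >= 0")
      floor(value)
    },
    degree = .step_lookup(value, caps$degree),
    cluster_coefficient = .step_lookup(value, caps$cluster_coefficient),
    ref_count = {
      if (any(value < 1 | value != round(value)))
        stop("invalid evidence: ref_count must be integer >= 1")
      .step_lookup(value, caps$ref_count)
    },
    preset_score = pmax(value, 0),
    stop("configuration error: unknown value_kind '", value_kind, "'")
  )
  pmin(pmax(s, 0), cap)
}

#' Score every row of an evidence table
#'
#' Adds a `score` column computed by [evidence_to_score()], dispatching on
#' each record's `value_kind` (and `is_log` for fold changes).
#'
#' @param records evidence data frame (see [read_evidence()] for columns).
#' @param caps score-transform configuration.
#' @return `records` with a numeric `score` column appended.
#' @export
score_evidence <- function(records, caps = default_score_caps()) {
  stopifnot(is.data.frame(records), all(c("value_kind", "value") %in% names(records)))
  if (is.null(records$is_log)) records$is_log <- FALSE
  records$is_log[is.na(records$is_log)] <- FALSE
  score <- numeric(nrow(records))
  for (kind in unique(records$value_kind)) {
    i <- which(records$value_kind == kind)
    if (kind == "fold_change") {
      for (lg in unique(records$is_log[i])) {
        j <- i[records$is_log[i] == lg]
        score[j] <- evidence_to_score(records$value[j], kind, is_log = lg, caps = caps)
      }
    } else {
      score[i] <- evidence_to_score(records$value[i], kind, caps = caps)
    }
  }
  records$score <- score
  records
}

#' Assign cold-treatment duration classes
#'
#' Exposure shorter than 12 h is short-term, 12-48 h (inclusive) mid-term,
#' longer than 48 h long-term. Missing durations (database evidence with no
#' treatment time) return `NA`.
#'
#' @param duration_hours numeric vector of treatment durations in hours.
#' @return character vector in `{"short","mid","long"}`, `NA` preserved.
#' @export
duration_class <- function(duration_hours) {
  out <- rep(NA_character_, length(duration_hours))
  ok <- !is.na(duration_hours)
  out[ok & duration_hours < 12] <- "short"
  out[ok & duration_hours >= 12 & duration_hours <= 48] <- "mid"
  out[ok & duration_hours > 48] <- "long"
  out
}

#' Canonical evidence layers
#' @return character vector of the five layer names in canonical order.
#' @export
evidence_layers <- function() c("DNA", "RNA", "protein", "function", "homologs")

#' Apply the study inclusion rules to an evidence table
#'
#' Keeps records from treatments below 15 degrees C (missing temperature,
#' e.g. database or homolog evidence, passes), keeps QTL records only when
#' the marker-trait association interval is within `qtl_cm_limit`
#' centimorgans, and collapses exact duplicates (same marker, layer, source
#' and value). Input order is preserved.
#'
#' @param records evidence data frame.
#' @param qtl_cm_limit maximum QTL association interval in cM (default 5).
#' @param max_temperature_C inclusion threshold, strict (default 15).
#' @return filtered evidence data frame.
#' @export
filter_evidence <- function(records, qtl_cm_limit = 5,
                            max_temperature_C = 15) {
  stopifnot(is.data.frame(records))
  keep <- rep(TRUE, nrow(records))
  if (!is.null(records$temperature_C)) {
    temp <- records$temperature_C
    keep <- keep & (is.na(temp) | temp < max_temperature_C)
  }
  if (!is.null(records$qtl_interval_cM)) {
    cm <- records$qtl_interval_cM
    keep <- keep & (is.na(cm) | cm <= qtl_cm_limit)
  }
  out <- records[keep, , drop = FALSE]
  key <- paste(out$marker_id, out$layer, out$source_id, out$value, sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a marker position to genes by windowed interval overlap
#'
#' A marker (point or interval, e.g. a QTL span) maps to every gene whose
#' body extended by `window_bp` on each side intersects it. Coordinates are
#' 1-based inclusive and the intersection is closed-interval.
#'
#' @param chrom chromosome name of the marker.
#' @param start,end marker position in bp (`end` defaults to `start`).
#' @param annotations gene annotation data frame with columns
#'   `gene_id`, `chrom`, `start`, `end`.
#' @param window_bp flanking window in bp (default 20000).
#' @return character vector of gene ids, sorted; empty (with a warning) for
#'   a chromosome absent from the annotation.
#' @export
map_marker_to_genes <- function(chrom, start, end = start, annotations,
                                window_bp = 20000) {
  stopifnot(start <= end)
  ann <- annotations[annotations$chrom == chrom, , drop = FALSE]
  if (nrow(ann) == 0L) {
    warning("chromosome '", chrom, "' not present in annotation")
    return(character(0))
  }
  hit <- (ann$start - window_bp) <= end & (ann$end + window_bp) >= start
  sort(ann$gene_id[hit])
}

#' Convert a homolog alignment table into homolog-layer evidence
#'
#' Precomputed protein-alignment hits of soybean genes against model-plant
#' genes are admitted when `e_value < 1e-10` and `identity_pct > 35`; each
#' surviving row becomes a reference-count record in the homologs layer
#' (scored later by the ref_count step function). Rows with missing
#' `e_value` or `identity_pct` are skipped with a warning.
#'
#' @param homolog_table data frame with columns `gene_id`, `model_gene`,
#'   `e_value`, `identity_pct`, `ref_count` (optional `source_id`).
#' @param e_value_max,identity_min filter thresholds.
#' @return evidence data frame (same columns as [read_evidence()]).
#' @export
score_homolog_evidence <- function(homolog_table, e_value_max = 1e-10,
                                   identity_min = 35) {
  stopifnot(is.data.frame(homolog_table))
  bad <- is.na(homolog_table$e_value) | is.na(homolog_table$identity_pct)
  if (any(bad)) {
    warning(sum(bad), " homolog row(s) with missing e-value/identity skipped")
    homolog_table <- homolog_table[!bad, , drop = FALSE]
  }
  keep <- homolog_table$e_value < e_value_max &
    homolog_table$identity_pct > identity_min
  ht <- homolog_table[keep, , drop = FALSE]
  if (is.null(ht$source_id)) ht$source_id <- paste0("homolog:", ht$model_gene)
  data.frame(
    marker_id = ht$gene_id,
    layer = "homologs",
    feature_type = "homolog",
    value_kind = "ref_count",
    value = as.numeric(ht$ref_count),
    is_log = FALSE,
    temperature_C = NA_real_,
    duration_hours = NA_real_,
    qtl_interval_cM = NA_real_,
    source_id = ht$source_id,
    stringsAsFactors = FALSE
  )
}

#' Convert protein-interaction pairs into per-gene degree evidence
#'
#' Protein-protein interaction evidence enters the protein layer as the
#' node degree of each gene on the supplied pair list, scored by the degree
#' step function.
#'
#' @param pairs data frame with columns `gene_a`, `gene_b` and optional
#'   `source_id`, `temperature_C`, `duration_hours`.
#' @return evidence data frame with one degree record per distinct gene.
#' @export
ppin_degree_evidence <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("gene_a", "gene_b") %in% names(pairs)))
  genes <- c(pairs$gene_a, pairs$gene_b)
  deg <- table(genes)
  src <- if (is.null(pairs$source_id)) "ppin" else pairs$source_id[1]
  data.frame(
    marker_id = names(deg),
    layer = "protein",
    feature_type = "protein_pair",
    value_kind = "degree",
    value = as.numeric(deg),
    is_log = FALSE,
    temperature_C = if (is.null(pairs$temperature_C)) NA_real_ else pairs$temperature_C[1],
    duration_hours = if (is.null(pairs$duration_hours)) NA_real_ else pairs$duration_hours[1],
    qtl_interval_cM = NA_real_,
    source_id = src,
    stringsAsFactors = FALSE
  )
}

#' Build per-duration-class gene score matrices
#'
#' The heart of the evidence-integration stage. Scored evidence records are
#' attached to genes (directly via `marker_id`, or through positional
#' mapping with [map_marker_to_genes()] when `chrom`/`pos_start` columns
#' are present and an annotation table is given), split into duration
#' classes (records without a treatment duration are duration-agnostic and
#' contribute to every class), and aggregated into a genes x layers score
#' matrix per class. Within a layer multiple records for one gene are
#' combined by `aggregate` ("max" keeps the per-layer 0-10 bound by
#' construction; "sum" is clipped at the cap). The combined score is
#' `W_j * sum_l S_jl` with a per-class duration weight, and genes whose
#' combined score is zero are removed.
#'
#' @param records scored, filtered evidence (must carry a `score` column;
#'   see [score_evidence()], [filter_evidence()]).
#' @param annotations optional gene annotation table for positional mapping.
#' @param weights named per-class duration weights `W`.
#' @param window_bp mapping window in bp.
#' @param aggregate within-layer aggregation, `"max"` or `"sum"`.
#' @param caps score-transform configuration (for the cap under `"sum"`).
#' @return named list of `gene_score_matrix` objects, one per duration
#'   class with at least one surviving gene.
#' @export
build_score_matrix <- function(records, annotations = NULL,
                               weights = c(short = 1, mid = 1, long = 1),
                               window_bp = 20000,
                               aggregate = c("max", "sum"),
                               caps = default_score_caps()) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.data.frame(records))
  if (is.null(records$score))
    stop("records must be scored first (see score_evidence)")
  stopifnot(all(c("short", "mid", "long") %in% names(weights)))

  # attach gene ids: positional mapping where available, else marker_id
  gene_of <- as.character(records$marker_id)
  rec_idx <- seq_len(nrow(records))
  if (!is.null(annotations) && !is.null(records$chrom)) {
    mapped_idx <- integer(0); mapped_gene <- character(0)
    has_pos <- !is.na(records$chrom) & !is.na(records$pos_start)
    for (i in which(has_pos)) {
      g <- suppressWarnings(map_marker_to_genes(
        records$chrom[i], records$pos_start[i],
        if (is.null(records$pos_end) || is.na(records$pos_end[i]))
          records$pos_start[i] else records$pos_end[i],
        annotations, window_bp))
      if (length(g)) {
        mapped_idx <- c(mapped_idx, rep.int(i, length(g)))
        mapped_gene <- c(mapped_gene, g)
      }
    }
    rec_idx <- c(which(!has_pos), mapped_idx)
    gene_of <- c(gene_of[!has_pos], mapped_gene)
  }

  layers <- evidence_layers()
  cls <- duration_class(records$duration_hours[rec_idx])
  out <- list()
  for (dc in c("short", "mid", "long")) {
    sel <- is.na(cls) | cls == dc
    idx <- rec_idx[sel]
    if (length(idx) == 0L) next
    df <- data.frame(gene = gene_of[sel],
                     layer = factor(records$layer[idx], levels = layers),
                     score = records$score[idx])
    genes <- sort(unique(df$gene))
    S <- matrix(0, nrow = length(genes), ncol = length(layers),
                dimnames = list(genes, layers))
    agg_fun <- if (aggregate == "max") max else sum
    agg <- tapply(df$score, list(df$gene, df$layer), agg_fun, default = 0)
    S[rownames(agg), colnames(agg)] <- agg
    S[is.na(S)] <- 0
    if (aggregate == "sum") S <- pmin(S, caps$cap)
    W <- rep(unname(weights[dc]), length(genes))
    combined <- W * rowSums(S)
    keep <- combined > 0
    if (!any(keep)) next
    out[[dc]] <- new_gene_score_matrix(dc, S[keep, , drop = FALSE],
                                       W[keep], combined[keep])
  }
  if (length(out) == 0L)
    stop("empty-matrix error: no gene survives with a nonzero combined score")
  out
}

new_gene_score_matrix <- function(duration_class, S, W, combined) {
  structure(list(duration_class = duration_class,
                 genes = rownames(S), layers = colnames(S),
                 S = S, W = W, combined = combined),
            class = "gene_score_matrix")
}

#' @export
print.gene_score_matrix <- function(x, ...) {
  cat(sprintf("gene score matrix [%s-term]: %d genes x %d layers, combined in [%.2f, %.2f]\n",
              x$duration_class, length(x$genes), length(x$layers),
              min(x$combined), max(x$combined)))
  invisible(x)
}
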