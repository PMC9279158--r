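# ---------------------------------------------------------------------------
# Nearest-template prediction of bulk transcriptomes with a gene-resampling
# permutation FDR, fibrosis flagging, and the layered IMF call.
# ---------------------------------------------------------------------------

#' Classify bulk samples by nearest template prediction
#'
#' The template of each class is +1 on its Up genes and -1 on its Down
#' genes over the union of signature genes present in the matrix, 0
#' elsewhere.  Each sample's signature-restricted z-vector is compared to
#' every template by cosine (default) or Pearson-correlation distance; the
#' nearest template is the prediction.  Significance: `n_perm` random gene
#' sets with the identical size/sign structure are drawn from all genes,
#' and `p = (1 + #{null distance <= observed}) / (1 + n_perm)`; BH across
#' samples; a sample is indeterminate when q >= `q_threshold`.
#'
#' @param bulk_z genes x samples matrix, z-scored per dataset.
#' @param signature a [signature_set()] (>= 10 genes present per class).
#' @param n_perm permutation count (default 1000).
#' @param q_threshold indeterminate cutoff (default 0.05; the stricter
#'   0.005 "robust" rule is a caller choice).
#' @param distance "cosine" or "correlation".
#' @param seed RNG seed for the permutations.
#' @return data.frame per sample: `prediction` (class or "indeterminate"),
#'   per-class distances, `p`, `q`, plus attributes `n_perm` and `seed`.
#' @export
ntp_classify <- function(bulk_z, signature, n_perm = 1000L,
                         q_threshold = 0.05,
                         distance = c("cosine", "correlation"),
                         seed = 1L) {
  distance <- match.arg(distance)
  classes <- names(signature$sets)
  all_genes <- rownames(bulk_z)
  union_genes <- intersect(signature_genes(signature), all_genes)
  for (cl in classes) {
    n_present <- length(intersect(c(signature$sets[[cl]]$up,
                                    signature$sets[[cl]]$down), all_genes))
    if (n_present < 10) stop("fewer than 10 signature genes present for class ", cl)
  }
  cov <- length(union_genes) / length(signature_genes(signature))
  if (cov < 0.5) warning("signature coverage below 50% (", round(100 * cov), "%)")
  Z <- as.matrix(bulk_z[union_genes, , drop = FALSE])
  templates <- sapply(classes, function(cl) {
    w <- numeric(length(union_genes))
    w[union_genes %in% signature$sets[[cl]]$up] <- 1
    w[union_genes %in% signature$sets[[cl]]$down] <- -1
    w
  })
  dist_to <- function(M, w) {
    if (distance == "cosine") {
      1 - as.vector(crossprod(M, w)) / (sqrt(colSums(M^2)) * sqrt(sum(w^2)))
    } else {
      1 - as.vector(cor(M, w))
    }
  }
  D <- sapply(seq_along(classes), function(i) dist_to(Z, templates[, i]))
  colnames(D) <- classes
  pred_i <- apply(D, 1, which.min)
  obs <- D[cbind(seq_len(nrow(D)), pred_i)]
  # permutation null: same size/sign structure on random genes
  set.seed(seed)
  exceed <- integer(ncol(Z))
  m <- length(union_genes)
  for (r in seq_len(n_perm)) {
    idx <- sample(length(all_genes), m)
    Zp <- as.matrix(bulk_z[idx, , drop = FALSE])
    dn <- sapply(seq_along(classes), function(i) dist_to(Zp, templates[, i]))
    if (is.null(dim(dn))) dn <- matrix(dn, ncol = length(classes))
    null_d <- dn[cbind(seq_len(nrow(dn)), pred_i)]
    exceed <- exceed + (null_d <= obs)
  }
  p <- (1 + exceed) / (1 + n_perm)
  q <- p.adjust(p, "BH")
  pred <- classes[pred_i]
  pred[q >= q_threshold] <- "indeterminate"
  out <- data.frame(sample_id = colnames(Z), prediction = pred,
                    nearest = classes[pred_i], D, p = p, q = q,
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "q_threshold") <- q_threshold
  out
}

#' Flag fibrotic samples
#'
#' F when the sample's CMS label is CMS4; for samples without a CMS label,
#' F when the fibroblast metagene exceeds the dataset quantile threshold.
#' The provenance of each call is recorded.
#'
#' @param bulk a [bulk_matrix()] (used for labels and, when needed, the
#'   metagene fallback; expression z-scored per dataset internally).
#' @param fibroblast_markers gene ids for the metagene fallback.
#' @param threshold_quantile metagene quantile above which a sample is F
#'   (default 0.75).
#' @return data.frame per sample: `fibrosis` ("F"/"NF"), `source`
#'   ("cms_label"/"metagene").
#' @export
fibrosis_flag <- function(bulk, fibroblast_markers = NULL,
                          threshold_quantile = 0.75) {
  stopifnot(inherits(bulk, "bulk_matrix"))
  cms <- bulk$samples$cms
  has_label <- cms != "unknown"
  f <- ifelse(cms == "CMS4", "F", "NF")
  src <- rep("cms_label", ncol(bulk$expr))
  if (any(!has_label)) {
    if (is.null(fibroblast_markers))
      stop("samples lack CMS labels and no fibroblast markers supplied")
    z <- zscore_within_cohort(bulk$expr, bulk$samples$cohort_id)
    sc <- metagene_score(z, fibroblast_markers)
    thr <- quantile(sc, threshold_quantile)
    f[!has_label] <- ifelse(sc[!has_label] > thr, "F", "NF")
    src[!has_label] <- "metagene"
  }
  data.frame(sample_id = bulk$samples$sample_id, fibrosis = f, source = src,
             stringsAsFactors = FALSE)
}

#' Layered IMF classification
#'
#' Combines the intrinsic subtype (I, from NTP), microsatellite status (M)
#' and fibrosis (F) into the five canonical classes: iCMS2_MSS_NF,
#' iCMS2_MSS_F, iCMS3_MSS_NF, iCMS3_MSS_F and iCMS3_MSI (MSI-H overrides
#' fibrosis in the class name).  iCMS2 with MSI-H is non_canonical;
#' indeterminate or missing layers give unclassified.
#'
#' @param ntp an [ntp_classify()] result whose classes are interpretable
#'   as iCMS2/iCMS3 (class names containing "2" map to iCMS2 etc.).
#' @param msi per-sample MSI labels ("MSI-H"/"MSS"/"unknown"), named by
#'   sample id or in NTP row order.
#' @param fibrosis a [fibrosis_flag()] result or per-sample "F"/"NF"
#'   vector.
#' @return data.frame per sample: `I`, `M`, `F`, `class`.
#' @export
imf_classify <- function(ntp, msi, fibrosis) {
  sid <- ntp$sample_id
  m <- if (!is.null(names(msi))) msi[sid] else msi
  f <- if (is.data.frame(fibrosis)) {
    setNames(fibrosis$fibrosis, fibrosis$sample_id)[sid]
  } else if (!is.null(names(fibrosis))) fibrosis[sid] else fibrosis
  I <- ifelse(grepl("2", ntp$prediction), "iCMS2",
              ifelse(grepl("3", ntp$prediction), "iCMS3", NA))
  I[ntp$prediction == "indeterminate"] <- NA
  cls <- character(length(sid))
  for (i in seq_along(sid)) {
    if (is.na(I[i]) || is.na(m[i]) || m[i] == "unknown" || is.na(f[i])) {
      cls[i] <- "unclassified"
    } else if (m[i] == "MSI-H") {
      cls[i] <- if (I[i] == "iCMS3") "iCMS3_MSI" else "non_canonical"
    } else {
      cls[i] <- paste0(I[i], "_MSS_", f[i])
    }
  }
  data.frame(sample_id = sid, I = I, M = unname(m), F = unname(f),
             class = cls, stringsAsFactors = FALSE)
}
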