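#' Radiomic extraction configuration
#'
#' Fixes the feature inventory: 14 shape descriptors (mask only, original
#' image), and 91 intensity/texture features (18 first-order, 22 GLCM,
#' 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM) on each of 12 intensity image
#' types (original, 8 stationary-wavelet sub-bands, LoG at sigma = 1, 2,
#' 3 mm), for 14 + 12 x 91 = 1,106 features per region and phase.
#' Intensities are discretized with a fixed bin width (default 25 HU) on
#' the windowed image.
#'
#' @param bin_width Discretization bin width in HU; default 25.
#' @param wavelet Include the 8 wavelet sub-bands; default `TRUE`.
#' @param log_sigmas_mm LoG scales in mm; default `c(1, 2, 3)`.
#' @return An `extraction_config` list, with `n_features` precomputed.
#' @export
extraction_config <- function(bin_width = 25, wavelet = TRUE,
                              log_sigmas_mm = c(1, 2, 3)) {
  n_filters <- 1L + (if (wavelet) 8L else 0L) + length(log_sigmas_mm)
  structure(
    list(bin_width = bin_width, wavelet = wavelet,
         log_sigmas_mm = log_sigmas_mm, n_filters = n_filters,
         n_features = 14L + n_filters * 91L),
    class = "extraction_config"
  )
}

texture_class_sizes <- function() {
  c(shape = 14L, first_order = 18L, glcm = 22L, glrlm = 16L, glszm = 16L,
    gldm = 14L, ngtdm = 5L)
}

#' Extract the full radiomic feature vector of one region
#'
#' Computes the configured inventory on one region: shape features from the
#' mask, and per filtered image the first-order and texture-matrix features
#' on intensities discretized at the configured bin width, with GLCM/GLRLM
#' (and all other texture families) aggregated over the 13 unique 3D
#' directions.
#'
#' @param images Named list of filtered 3D arrays from [derive_images()].
#' @param mask A `mask_volume` on the same grid (the region).
#' @param config An `extraction_config`.
#' @return Named numeric vector of length `config$n_features`, names
#'   `{filter}__{class}__{feature}` (shape: `original__shape__{feature}`).
#' @export
extract_region_features <- function(images, mask, config = extraction_config()) {
  stopifnot(inherits(mask, "mask_volume"))
  n_vox <- sum(mask$labels)
  if (n_vox < 2) {
    stop(structure(
      class = c("habitatct_degenerate_region", "error", "condition"),
      list(message = sprintf("region has %d voxel(s); shape and texture are undefined", n_vox),
           call = sys.call())))
  }
  out <- numeric(0)
  sh <- shape_features(mask)
  names(sh) <- paste0("original__shape__", names(sh))
  out <- c(out, sh)

  voxvol <- prod(mask$spacing)
  in_mask <- mask$labels == 1L
  for (fname in names(images)) {
    arr <- images[[fname]]
    x <- arr[in_mask]
    fo <- first_order_features(x, config$bin_width, voxvol)
    names(fo) <- paste0(fname, "__first_order__", names(fo))

    dg <- discretize_region(arr, mask$labels, config$bin_width)
    tx_list <- list(glcm = glcm_features(dg$G, dg$Ng),
                    glrlm = glrlm_features(dg$G, dg$Ng, dg$n),
                    glszm = glszm_features(dg$G, dg$Ng, dg$n),
                    gldm = gldm_features(dg$G, dg$Ng),
                    ngtdm = ngtdm_features(dg$G, dg$Ng))
    tx <- unlist(lapply(names(tx_list), function(cl) {
      stats::setNames(tx_list[[cl]],
                      paste0(fname, "__", cl, "__", names(tx_list[[cl]])))
    }))
    out <- c(out, fo, tx)
  }
  out
}

#' Build the cohort feature tables
#'
#' Runs the full extraction for every patient and assembles the three
#' modelling tables: whole-tumor (`radiomics`), peritumoral rings (`peri`,
#' one table per radius, ring region only), and the pre-fusion habitat
#' table (`ith`, the per-subregion feature blocks concatenated). Column
#' names follow `{phase}__{region}__{filter}__{class}__{feature}`. With the
#' default configuration and 4 phases the widths are 4,424 (radiomics),
#' 4,424 per ring, and 13,272 (ith).
#'
#' Habitat subregions that are absent for a patient, or too small for
#' texture (fewer than 2 voxels), yield missing entries that are imputed
#' with the cohort median of each affected column (with a message); this
#' keeps patients rather than dropping them.
#'
#' @param patients Named list of `synthetic_patient` objects (or any list
#'   with `phases` and a tumor mask field).
#' @param habitats Named list (by patient) of gap-filled `habitat_map`s.
#' @param rings Named list (by patient) of named lists of ring
#'   `mask_volume`s (e.g. `list(ring1 = ..., ring3 = ..., ring5 = ...)`).
#' @param config An `extraction_config`.
#' @param tables Which tables to build; subset of
#'   `c("radiomics", "peri", "ith")`.
#' @param mask_field Which reader's tumor mask to use; default
#'   `"tumor_mask_reader1"`.
#' @param window_width,window_level HU display window applied before
#'   filtering and intensity extraction (shape uses the mask only).
#' @return List with elements `radiomics` (tibble), `peri` (named list of
#'   tibbles), `ith` (tibble); each tibble has a `patient_id` column first.
#' @export
build_feature_tables <- function(patients, habitats = NULL, rings = NULL,
                                 config = extraction_config(),
                                 tables = c("radiomics", "peri", "ith"),
                                 mask_field = "tumor_mask_reader1",
                                 window_width = 300, window_level = 25) {
  tables <- match.arg(tables, several.ok = TRUE)
  if ("ith" %in% tables && is.null(habitats)) {
    stop("missing inputs for the ith table: `habitats`")
  }
  if ("peri" %in% tables && is.null(rings)) {
    stop("missing inputs for the peri tables: `rings`")
  }
  ids <- names(patients)
  if (is.null(ids)) ids <- vapply(patients, function(p) p$patient_id, "")

  rad_rows <- list(); ith_rows <- list()
  ring_names <- if (!is.null(rings)) names(rings[[1]]) else character()
  peri_rows <- stats::setNames(vector("list", length(ring_names)), ring_names)

  for (pi in seq_along(patients)) {
    p <- patients[[pi]]
    id <- ids[pi]
    tumor <- p[[mask_field]]
    rad_vec <- numeric(0); ith_vec <- numeric(0)
    peri_vec <- stats::setNames(vector("list", length(ring_names)), ring_names)
    for (rn in ring_names) peri_vec[[rn]] <- numeric(0)

    for (ph in names(p$phases)) {
      vol <- window_hu(p$phases[[ph]], window_width, window_level)
      imgs <- derive_images(vol, wavelet = config$wavelet,
                            log_sigmas_mm = config$log_sigmas_mm)
      prefix <- function(region, v) {
        stats::setNames(v, paste0(ph, "__", region, "__", names(v)))
      }
      if ("radiomics" %in% tables) {
        rad_vec <- c(rad_vec, prefix("tumor",
                                     extract_region_features(imgs, tumor, config)))
      }
      if ("peri" %in% tables) {
        for (rn in ring_names) {
          peri_vec[[rn]] <- c(peri_vec[[rn]], prefix(
            rn, extract_region_features(imgs, rings[[id]][[rn]], config)))
        }
      }
      if ("ith" %in% tables) {
        hab <- habitats[[id]]
        # either one map reused across phases, or a per-phase named list
        if (!inherits(hab, "habitat_map")) hab <- hab[[ph]]
        for (h in 1:3) {
          region <- paste0("habitat", h)
          sub <- if (h <= hab$k) habitat_submask(hab, h) else NULL
          vec <- degenerate_safe_extract(imgs, sub, config)
          ith_vec <- c(ith_vec, prefix(region, vec))
        }
      }
    }
    if ("radiomics" %in% tables) rad_rows[[id]] <- rad_vec
    if ("peri" %in% tables) for (rn in ring_names) {
      peri_rows[[rn]][[id]] <- peri_vec[[rn]]
    }
    if ("ith" %in% tables) ith_rows[[id]] <- ith_vec
  }

  out <- list()
  if ("radiomics" %in% tables) out$radiomics <- rows_to_table(rad_rows)
  if ("peri" %in% tables) {
    out$peri <- lapply(peri_rows, rows_to_table)
  }
  if ("ith" %in% tables) out$ith <- rows_to_table(ith_rows)
  out
}

# Extract, returning an all-NA vector of the right shape for degenerate
# regions (absent habitat or < 2 voxels); imputed later cohort-wide.
degenerate_safe_extract <- function(imgs, mask, config) {
  if (!is.null(mask) && sum(mask$labels) >= 2) {
    return(extract_region_features(imgs, mask, config))
  }
  template <- feature_name_template(config, names(imgs))
  stats::setNames(rep(NA_real_, length(template)), template)
}

feature_name_template <- function(config, filter_names) {
  c(paste0("original__shape__", shape_names()),
    unlist(lapply(filter_names, function(fname) {
      c(paste0(fname, "__first_order__", first_order_names()),
        paste0(fname, "__glcm__", glcm_names()),
        paste0(fname, "__glrlm__", srlm_names("run", "length")),
        paste0(fname, "__glszm__", srlm_names("zone", "size")),
        paste0(fname, "__gldm__", gldm_names()),
        paste0(fname, "__ngtdm__", ngtdm_names()))
    })))
}

rows_to_table <- function(rows) {
  m <- do.call(rbind, rows)
  tab <- tibble::as_tibble(m)
  # cohort-median imputation of degenerate-region columns
  if (anyNA(m)) {
    nac <- which(colSums(is.na(m)) > 0)
    message(sprintf("imputing %d degenerate-region feature entries with cohort medians",
                    sum(is.na(m))))
    for (jc in nac) {
      med <- median(m[, jc], na.rm = TRUE)
      if (!is.finite(med)) med <- 0
      tab[[jc]][is.na(tab[[jc]])] <- med
    }
  }
  dplyr::bind_cols(tibble::tibble(patient_id = rownames(m)), tab)
}

glcm_names <- function() {
  c("autocorrelation", "joint_average", "cluster_prominence",
    "cluster_shade", "cluster_tendency", "contrast", "correlation",
    "difference_average", "difference_entropy", "difference_variance",
    "joint_energy", "joint_entropy", "imc1", "imc2", "idm", "idmn", "id",
    "idn", "inverse_variance", "maximum_probability", "sum_entropy",
    "sum_squares")
}

srlm_names <- function(prefix, size_name) {
  short_tag <- if (prefix == "run") "short_run" else "small_area"
  long_tag <- if (prefix == "run") "long_run" else "large_area"
  c(paste0(short_tag, "_emphasis"), paste0(long_tag, "_emphasis"),
    "gray_level_nonuniformity", "gray_level_nonuniformity_normalized",
    paste0(prefix, "_", size_name, "_nonuniformity"),
    paste0(prefix, "_", size_name, "_nonuniformity_normalized"),
    paste0(prefix, "_percentage"), "gray_level_variance",
    paste0(prefix, "_variance"), paste0(prefix, "_entropy"),
    "low_gray_level_emphasis", "high_gray_level_emphasis",
    paste0(short_tag, "_low_gray_level_emphasis"),
    paste0(short_tag, "_high_gray_level_emphasis"),
    paste0(long_tag, "_low_gray_level_emphasis"),
    paste0(long_tag, "_high_gray_level_emphasis"))
}

gldm_names <- function() {
  c("small_dependence_emphasis", "large_dependence_emphasis",
    "gray_level_nonuniformity", "dependence_nonuniformity",
    "dependence_nonuniformity_normalized", "gray_level_variance",
    "dependence_variance", "dependence_entropy", "low_gray_level_emphasis",
    "high_gray_level_emphasis", "small_dependence_low_gray_level_emphasis",
    "small_dependence_high_gray_level_emphasis",
    "large_dependence_low_gray_level_emphasis",
    "large_dependence_high_gray_level_emphasis")
}

ngtdm_names <- function() {
  c("coarseness", "contrast", "busyness", "complexity", "strength")
}
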