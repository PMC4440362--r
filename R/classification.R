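#' Quantitative spine shape features
#'
#' Extracts the features used for spine typing from the 3D skeleton path
#' and anisotropic distance transform of one spine mask, all in physical
#' units: total length (neck base to tip along the skeleton), neck diameter
#' (minimal cross-section over the proximal path), head diameter (maximal
#' inscribed ball in the distal part), the head/neck and length/neck
#' ratios, and the head count.  Masks too small to skeletonize (fewer than
#' `min_voxels` voxels) are flagged `too_small` and treated as not fully
#' reconstructable.
#'
#' @param mask a connected [voxel_mask] of one spine; if it carries a
#'   `base_nm` attribute (set by [split_dendrite()]) the skeleton is rooted
#'   there, otherwise at one end of the geodesic diameter.
#' @param min_voxels minimal mask size for feature extraction.
#' @return A one-row data.frame: `length_nm`, `neck_diam_nm`,
#'   `head_diam_nm`, `head_neck_ratio`, `length_neck_ratio`, `head_count`,
#'   `too_small`.
#' @export
extract_features <- function(mask, min_voxels = 8L) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!length(mask$idx)) stop("empty spine mask")
  if (length(mask$idx) < min_voxels)
    return(data.frame(length_nm = NA_real_, neck_diam_nm = NA_real_,
                      head_diam_nm = NA_real_, head_neck_ratio = NA_real_,
                      length_neck_ratio = NA_real_, head_count = NA_integer_,
                      too_small = TRUE))
  geom <- spine_geometry(mask)
  heads <- detect_heads(geom, mask$spacing)
  distal <- !is.na(geom$dist) & geom$dist >= 0.55 * geom$length_s
  head_diam <- 2 * max(geom$edt[distal], geom$edt[heads$centers])
  neck_diam <- 2 * heads$r_neck
  data.frame(length_nm = geom$length,
             neck_diam_nm = neck_diam,
             head_diam_nm = head_diam,
             head_neck_ratio = head_diam / neck_diam,
             length_neck_ratio = geom$length / neck_diam,
             head_count = heads$n,
             too_small = FALSE)
}

#' Classification thresholds
#'
#' Numeric cut-offs for the decision cascade in [classify_spine()].  The
#' morphological classes are qualitative in origin; these defaults
#' operationalize them and are deliberately exposed for adjustment.
#'
#' @param t_stub maximal length/neck ratio of a stubby spine.
#' @param t_head minimal head diameter (nm) of a mushroom spine.
#' @param t_ratio minimal head/neck ratio of a mushroom spine.
#' @param t_filo maximal head/neck ratio of a filopodial spine.
#' @param t_len minimal length/neck ratio of a filopodial spine.
#' @return A named list of thresholds.
#' @export
spine_thresholds <- function(t_stub = 1.8, t_head = 350, t_ratio = 1.5,
                             t_filo = 1.25, t_len = 3) {
  list(t_stub = t_stub, t_head = t_head, t_ratio = t_ratio,
       t_filo = t_filo, t_len = t_len)
}

#' Assign a spine to one of five morphological classes
#'
#' Total decision cascade over the quantitative features, in fixed order:
#' branched if more than one head arises from the single neck; else stubby
#' if the spine length is similar to the neck width
#' (`length/neck <= t_stub`); else mushroom if tipped by a large head
#' (`head_diam >= t_head` and `head/neck >= t_ratio`); else filopodial if
#' long and thin with similar neck and head diameters
#' (`head/neck < t_filo` and `length/neck >= t_len`); else thin (small
#' neck tipped by a small round head).
#'
#' @param features a feature row from [extract_features()] (or a list with
#'   the same fields).
#' @param thresholds a list from [spine_thresholds()].
#' @return One of `"thin"`, `"filopodial"`, `"stubby"`, `"mushroom"`,
#'   `"branched"`.
#' @export
classify_spine <- function(features, thresholds = spine_thresholds()) {
  f <- as.list(features)
  if (isTRUE(f$too_small))
    stop("spine flagged too_small cannot be classified")
  th <- thresholds
  if (f$head_count >= 2L) return("branched")
  if (f$length_neck_ratio <= th$t_stub) return("stubby")
  if (f$head_diam_nm >= th$t_head && f$head_neck_ratio >= th$t_ratio)
    return("mushroom")
  if (f$head_neck_ratio < th$t_filo && f$length_neck_ratio >= th$t_len)
    return("filopodial")
  "thin"
}

#' Spine-type composition table
#'
#' Counts and integer percentages per morphological class.  Percentages are
#' rounded to the nearest integer with a largest-remainder correction so
#' the table always sums to 100.
#'
#' @param types character vector of spine types (one entry per spine).
#' @param branched_head_types optional vector of types assigned to the
#'   individualized heads of branched spines, reported as a second table.
#' @return A data.frame `type`, `n`, `pct`; if `branched_head_types` is
#'   given, the head sub-table is attached as the `branched_heads`
#'   attribute.
#' @export
type_composition <- function(types, branched_head_types = NULL) {
  if (!length(types)) stop("no spine records")
  bad <- setdiff(unique(types), spine_types())
  if (length(bad)) stop("unknown spine type(s): ", toString(bad))
  n <- vapply(spine_types(), function(t) sum(types == t), integer(1))
  out <- data.frame(type = spine_types(), n = unname(n),
                    pct = largest_remainder_pct(unname(n)))
  rownames(out) <- NULL
  if (!is.null(branched_head_types))
    attr(out, "branched_heads") <- type_composition(branched_head_types)
  out
}
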