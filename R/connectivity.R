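#' Build the spine-synapse-bouton graph
#'
#' Links every synaptic junction to its presynaptic bouton and its
#' postsynaptic element by 26-adjacency of label voxels (minimum contact
#' configurable).  Each junction must touch exactly one bouton; junctions
#' touching zero or several boutons raise an ambiguity error listing the
#' offending ids.  Synapses made on the same spine by different boutons
#' stay distinct records, and spines with no junction are flagged
#' non-synaptic.
#'
#' @param seg a [voxel_segmentation] whose object table categorizes labels
#'   as `dendrite_shaft` / `spine` / `synaptic_junction` / `bouton`; an
#'   optional `labeled` column marks the DAB-traced elements.
#' @param min_contact minimal number of touching voxel pairs for a link.
#' @return A list of class `connectivity_graph` with data.frames
#'   `synapses` (`synapse_id`, `bouton_id`, `post_id`, `post_category`,
#'   `post_labeled`, `location`), `boutons` (`bouton_id`, `sbi`, `class`,
#'   `n_synapses`, `synapse_ids`) and `spines` (`spine_id`, `labeled`,
#'   `n_synapses`, `nonsynaptic`).
#' @export
build_graph <- function(seg, min_contact = 1L) {
  stopifnot(inherits(seg, "voxel_segmentation"))
  obj <- seg$objects
  cat_of <- setNames(obj$category, obj$id)
  labeled_of <- if ("labeled" %in% names(obj))
    setNames(obj$labeled, obj$id)
  else setNames(rep(NA, nrow(obj)), obj$id)

  adj <- cpp_label_adjacency(seg$labels, dim(seg$labels))
  adj <- adj[adj$n_contact >= min_contact, , drop = FALSE]

  syn_ids <- obj$id[obj$category == "synaptic_junction"]
  if (!length(syn_ids)) stop("segmentation contains no synaptic junctions")
  recs <- lapply(syn_ids, function(s) {
    nb <- rbind(
      data.frame(other = adj$b[adj$a == s], n = adj$n_contact[adj$a == s]),
      data.frame(other = adj$a[adj$b == s], n = adj$n_contact[adj$b == s]))
    nb$category <- unname(cat_of[as.character(nb$other)])
    bout <- nb[nb$category == "bouton", , drop = FALSE]
    if (nrow(bout) != 1L)
      stop(sprintf(
        "synapse %d is adjacent to %d boutons (%s); cannot resolve",
        s, nrow(bout), toString(bout$other)))
    post <- nb[nb$category %in% c("spine", "dendrite_shaft"), ,
               drop = FALSE]
    if (!nrow(post))
      stop(sprintf("synapse %d touches no postsynaptic element", s))
    post <- post[which.max(post$n), , drop = FALSE]
    data.frame(synapse_id = s, bouton_id = bout$other[1L],
               post_id = post$other[1L], post_category = post$category[1L],
               post_labeled = unname(labeled_of[as.character(post$other[1L])]),
               location = NA_character_)
  })
  synapses <- do.call(rbind, recs)

  boutons <- do.call(rbind, lapply(split(synapses, synapses$bouton_id),
    function(ss) {
      sbi <- length(unique(ss$post_id))
      data.frame(bouton_id = ss$bouton_id[1L], sbi = sbi,
                 class = if (sbi == 1L) "SSB" else "MSB",
                 n_synapses = nrow(ss),
                 synapse_ids = paste(sort(ss$synapse_id), collapse = ";"))
    }))
  rownames(boutons) <- NULL

  spine_ids <- obj$id[obj$category == "spine"]
  spines <- data.frame(
    spine_id = spine_ids,
    labeled = unname(labeled_of[as.character(spine_ids)]),
    n_synapses = vapply(spine_ids,
                        function(s) sum(synapses$post_id == s), integer(1)))
  spines$nonsynaptic <- spines$n_synapses == 0L

  structure(list(synapses = synapses, boutons = boutons, spines = spines),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf(
    "<connectivity_graph> %d synapses, %d boutons (%d SSB / %d MSB), %d spines\n",
    nrow(x$synapses), nrow(x$boutons), sum(x$boutons$class == "SSB"),
    sum(x$boutons$class == "MSB"), nrow(x$spines)))
  invisible(x)
}

#' Head/neck partition of a spine
#'
#' Splits a spine mask into its head region (voxels within the detected
#' head ball(s), i.e. geodesically distal beyond the neck) and the
#' remaining neck region, for synapse-location calls.
#'
#' @param mask a [voxel_mask] of one spine.
#' @return A list with `head` and `neck` [voxel_mask]s (the neck mask may
#'   be empty for stubby spines).
#' @export
spine_head_partition <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  geom <- spine_geometry(mask)
  heads <- detect_heads(geom, mask$spacing)
  head_diam <- 2 * max(geom$edt[heads$centers])
  cut <- max(geom$length_s - 1.2 * head_diam, 0)
  sel <- !is.na(geom$dist[geom$idx_loc]) &
    geom$dist[geom$idx_loc] >= cut
  head_idx <- uncrop_idx(geom$idx_loc[sel], geom$crop, mask$dim)
  list(head = mask_like(mask, head_idx),
       neck = mask_like(mask, setdiff(mask$idx, head_idx)))
}

#' Locate a synapse on the head or neck of its spine
#'
#' The junction's contact voxels (junction voxels 26-adjacent to the spine)
#' are attributed to the head or neck partition; the majority region wins
#' and exact ties go to the head.
#'
#' @param spine_mask the spine [voxel_mask].
#' @param junction_mask the synaptic-junction [voxel_mask].
#' @param partition optional precomputed [spine_head_partition()] result.
#' @return `"head"` or `"neck"`.
#' @export
synapse_location <- function(spine_mask, junction_mask, partition = NULL) {
  stopifnot(inherits(spine_mask, "voxel_mask"),
            inherits(junction_mask, "voxel_mask"))
  if (is.null(partition)) partition <- spine_head_partition(spine_mask)
  d <- spine_mask$dim
  head_arr <- array(FALSE, d); head_arr[partition$head$idx] <- TRUE
  neck_arr <- array(FALSE, d); neck_arr[partition$neck$idx] <- TRUE
  n_head <- sum(adjacent_to(junction_mask$idx, head_arr, d))
  n_neck <- sum(adjacent_to(junction_mask$idx, neck_arr, d))
  if (n_head + n_neck == 0L) stop("junction does not touch the spine")
  if (n_head >= n_neck) "head" else "neck"
}

#' SSB/MSB summary
#'
#' Fractions of single- (SBi = 1) and multi-synaptic (SBi >= 2) boutons as
#' integer percentages (largest-remainder rounded so they sum to 100), the
#' SBi histogram, and the mean number of synaptic contacts established by
#' MSBs.
#'
#' @param boutons the `boutons` table of a [build_graph()] result (needs
#'   columns `sbi` and `class`).
#' @return A list `n`, `n_ssb`, `pct_ssb`, `pct_msb`, `sbi_histogram`,
#'   `mean_msb_contacts`.
#' @export
ssb_msb_summary <- function(boutons) {
  if (!nrow(boutons)) stop("no boutons")
  n <- nrow(boutons)
  n_ssb <- sum(boutons$sbi == 1L)
  pct <- largest_remainder_pct(c(n_ssb, n - n_ssb))
  hist <- vapply(seq_len(max(boutons$sbi, 10L)),
                 function(k) sum(boutons$sbi == k), integer(1))
  msb <- boutons$sbi[boutons$sbi >= 2L]
  list(n = n, n_ssb = n_ssb, pct_ssb = pct[1L], pct_msb = pct[2L],
       sbi_histogram = setNames(hist, seq_along(hist)),
       mean_msb_contacts = if (length(msb)) mean(msb) else NA_real_)
}

#' SSB/MSB fractions per spine type
#'
#' Contingency of bouton class against the type of the labeled postsynaptic
#' spine, with per-type percentages and the overall reference row.
#'
#' @param graph a [build_graph()] result.
#' @param spine_types data.frame with `spine_id` and `type` for every
#'   labeled spine.
#' @return A data.frame `type`, `n_ssb`, `n_msb`, `pct_ssb`, `pct_msb`,
#'   with an `"overall"` row appended.
#' @export
ssb_msb_by_type <- function(graph, spine_types) {
  stopifnot(inherits(graph, "connectivity_graph"))
  syn <- graph$synapses
  lab <- syn[!is.na(syn$post_labeled) & syn$post_labeled &
             syn$post_category == "spine", , drop = FALSE]
  if (!nrow(lab)) stop("no synapses on labeled spines")
  ty <- spine_types$type[match(lab$post_id, spine_types$spine_id)]
  if (anyNA(ty))
    stop("labeled spine(s) without a type: ",
         toString(unique(lab$post_id[is.na(ty)])))
  cls <- graph$boutons$class[match(lab$bouton_id, graph$boutons$bouton_id)]
  tab <- table(factor(ty, levels = spine_types_present(ty)),
               factor(cls, levels = c("SSB", "MSB")))
  out <- data.frame(type = rownames(tab), n_ssb = as.integer(tab[, "SSB"]),
                    n_msb = as.integer(tab[, "MSB"]))
  out <- rbind(out, data.frame(type = "overall",
                               n_ssb = sum(out$n_ssb),
                               n_msb = sum(out$n_msb)))
  pct <- t(apply(out[, c("n_ssb", "n_msb")], 1L, largest_remainder_pct))
  out$pct_ssb <- pct[, 1L]
  out$pct_msb <- pct[, 2L]
  rownames(out) <- NULL
  out
}

spine_types_present <- function(ty) {
  c(intersect(spine_types(), unique(ty)),
    setdiff(unique(ty), spine_types()))
}
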