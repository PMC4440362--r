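test_that("the recovered wiring graph equals the ground truth", {
  spec <- coarse_spec(c(thin = 1, mushroom = 1, stubby = 1), seed = 19,
                      sbi = c(.3, .3, .2, .2, rep(0, 6)))
  ph <- build_phantom(spec, render_intensity = FALSE)
  g <- build_graph(ph$segmentation)
  truth <- ph$truth
  tsyn <- truth[truth$category == "synaptic_junction", ]
  expect_equal(nrow(g$synapses), nrow(tsyn))
  ord <- match(g$synapses$synapse_id, tsyn$id)
  expect_equal(g$synapses$bouton_id, tsyn$bouton_id[ord])
  expect_equal(g$synapses$post_id, tsyn$post_id[ord])
  tb <- truth[truth$category == "bouton", ]
  expect_equal(g$boutons$sbi[match(tb$id, g$boutons$bouton_id)], tb$sbi)
  # each synapse counted once: SBi sums to the synapse count
  expect_equal(sum(g$boutons$sbi), nrow(g$synapses))
})

test_that("non-synaptic spines are flagged", {
  spec <- coarse_spec(c(thin = 1, mushroom = 1), seed = 23)
  spec$nonsynaptic_fraction <- 1  # all spines vacant
  ph <- build_phantom(spec, render_intensity = FALSE)
  expect_error(build_graph(ph$segmentation), "no synaptic junctions")

  spec2 <- coarse_spec(c(thin = 1, mushroom = 1), seed = 24)
  ph2 <- build_phantom(spec2, render_intensity = FALSE)
  g <- build_graph(ph2$segmentation)
  lab_spines <- g$spines[!is.na(g$spines$labeled) & g$spines$labeled, ]
  expect_true(all(!lab_spines$nonsynaptic))
})

test_that("ambiguous bouton adjacency raises with the offending ids", {
  lab <- array(0L, c(10, 10, 4))
  lab[5, 2:3, 2] <- 1L   # spine
  lab[5, 4, 2] <- 2L     # synapse touching two boutons
  lab[5, 5, 2] <- 3L     # bouton A
  lab[4, 4, 2] <- 4L     # bouton B
  seg <- voxel_segmentation(lab, data.frame(
    id = 1:4, category = c("spine", "synaptic_junction", "bouton",
                           "bouton")), c(10, 10, 25))
  expect_error(build_graph(seg), "2 boutons")
})

test_that("synapse location follows the majority contact with head ties", {
  m <- clean_spine_mask("mushroom", 901)
  tr <- attr(m, "truth")
  # junction rendered on the head pole locates to the head
  spec <- phantom_spec(spacing = c(3.7, 3.7, 25),
                       n_spines_per_type = c(mushroom = 1),
                       sbi_distribution = c(1, rep(0, 9)),
                       nonsynaptic_fraction = 0, neck_synapse_fraction = 0,
                       rng_seed = 9)
  ph <- build_phantom(spec, render_intensity = FALSE)
  t2 <- ph$truth
  sm <- object_mask(ph$segmentation,
                    t2$id[t2$category == "spine" & t2$labeled])
  b <- attr(t2, "bases")
  attr(sm, "base_nm") <- c(b$x[1], b$y[1], b$z[1])
  jm <- object_mask(ph$segmentation,
                    t2$id[t2$category == "synaptic_junction"][1])
  expect_equal(synapse_location(sm, jm), "head")

  # junction on the neck locates to the neck
  spec$neck_synapse_fraction <- 1
  ph3 <- build_phantom(spec, render_intensity = FALSE)
  t3 <- ph3$truth
  sm3 <- object_mask(ph3$segmentation,
                     t3$id[t3$category == "spine" & t3$labeled])
  b3 <- attr(t3, "bases")
  attr(sm3, "base_nm") <- c(b3$x[1], b3$y[1], b3$z[1])
  jm3 <- object_mask(ph3$segmentation,
                     t3$id[t3$category == "synaptic_junction"][1])
  expect_equal(t3$location[t3$category == "synaptic_junction"][1], "neck")
  expect_equal(synapse_location(sm3, jm3), "neck")

  # an exact 50/50 straddle resolves to the head by convention
  part <- spine_head_partition(sm)
  fake <- voxel_mask(c(part$head$idx[1], part$neck$idx[1]), sm$dim,
                     sm$spacing)
  expect_equal(synapse_location(sm, fake, partition = part), "head")
  off <- voxel_mask(1L, sm$dim, sm$spacing)
  expect_error(synapse_location(sm, off, partition = part), "touch")
})

test_that("SSB/MSB summary reproduces printed worked examples", {
  boutons <- data.frame(sbi = c(rep(1L, 6), rep(2L, 11), rep(3L, 4),
                                rep(4L, 4)))
  boutons$class <- ifelse(boutons$sbi == 1L, "SSB", "MSB")
  s <- ssb_msb_summary(boutons)
  expect_equal(s$n, 25L)
  expect_equal(s$pct_ssb, 24L)
  expect_equal(s$pct_msb, 76L)
  expect_equal(s$pct_ssb + s$pct_msb, 100L)

  all_ssb <- data.frame(sbi = rep(1L, 7), class = rep("SSB", 7))
  expect_equal(ssb_msb_summary(all_ssb)$pct_ssb, 100L)

  mixed <- data.frame(sbi = c(1L, 3L, 7L), class = c("SSB", "MSB", "MSB"))
  s2 <- ssb_msb_summary(mixed)
  expect_equal(s2$mean_msb_contacts, 5)
  expect_equal(unname(s2$sbi_histogram[c(1, 3, 7)]), c(1L, 1L, 1L))
})

test_that("per-type SSB/MSB fractions recover type-uniform and biased wiring", {
  g <- list(synapses = data.frame(
    synapse_id = 1:8, bouton_id = c(1, 2, 3, 4, 5, 6, 7, 8),
    post_id = c(11, 12, 13, 14, 11, 12, 13, 14),
    post_category = "spine", post_labeled = TRUE,
    location = "head"),
    boutons = data.frame(bouton_id = 1:8,
                         sbi = c(1, 1, 1, 1, 3, 3, 3, 3),
                         class = rep(c("SSB", "MSB"), each = 4),
                         n_synapses = 1, synapse_ids = as.character(1:8)),
    spines = data.frame(spine_id = 11:14, labeled = TRUE, n_synapses = 2,
                        nonsynaptic = FALSE))
  class(g) <- "connectivity_graph"
  st <- data.frame(spine_id = 11:14,
                   type = c("thin", "thin", "mushroom", "mushroom"))
  tab <- ssb_msb_by_type(g, st)
  # uniform wiring: per-type fractions equal the overall fraction
  expect_true(all(tab$pct_ssb == 50L))
  expect_equal(tab$type[nrow(tab)], "overall")

  st1 <- data.frame(spine_id = 11:14, type = "thin")
  tab1 <- ssb_msb_by_type(g, st1)
  expect_equal(nrow(tab1), 2L)  # one type row + overall
  expect_error(ssb_msb_by_type(g, st[1:2, ]), "without a type")
})
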