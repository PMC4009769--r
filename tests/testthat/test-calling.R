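## Clustering, orientation, novelty and event formatting.

test_that("anchors cluster by proximity within the insert-size window", {
  ## window = 150 + 3 * 50 = 300
  params <- calling_params(insert_mean = 150, insert_sd = 50)
  ev <- dplyr::bind_rows(
    ev_cluster(100, "MuDR", "TE_MUDR1", p = 1, spread = 0),
    ev_cluster(150, "MuDR", "TE_MUDR1", p = 1, spread = 0),
    ev_cluster(900, "MuDR", "TE_MUDR1", p = 1, spread = 0))
  cl <- cluster_anchors(ev, params)
  parts <- split(cl$anchor_pos, cl$cluster_id)
  expect_equal(length(parts), 2)
  expect_setequal(vapply(parts, paste, collapse = ",", character(1)),
                  c("100,150", "900"))

  single <- cluster_anchors(ev_cluster(5, "MuDR", "TE_MUDR1", p = 1), params)
  expect_equal(length(unique(single$cluster_id)), 1)

  ## co-located anchors of different items never share a cluster
  both <- dplyr::bind_rows(
    ev_cluster(1000, "Copia", "TE_COP1", p = 2),
    ev_cluster(1000, "Gypsy", "TE_GYP1", p = 2))
  cl2 <- cluster_anchors(both, params)
  expect_equal(length(unique(cl2$cluster_id)), 2)
  expect_equal(nrow(dplyr::distinct(cl2, cluster_id, item)), 2)
})

test_that("sweep clustering agrees with a brute-force single-linkage oracle", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(2:200, 1)
    window <- sample(50:500, 1)
    pos <- sort(sample.int(5000, n, replace = TRUE))
    params <- calling_params(insert_mean = window / 2, insert_sd = window / 6)
    stopifnot(abs(cluster_window(params) - window) < 1e-9)
    ev <- tibble::tibble(individual_id = "i", read_name = paste0("r", 1:n),
                         anchor_chrom = "c", anchor_pos = pos,
                         anchor_strand = "+", anchor_mapq = 60L,
                         te_id = "TE_COP1", te_strand = "+",
                         te_mate_strand = "-", item = "Copia")
    cl <- cluster_anchors(ev, params)
    got <- canon_partition(cl$cluster_id[order(cl$anchor_pos)])
    want <- canon_partition(brute_single_linkage(pos, window))
    expect_equal(got, want)
  }
})

test_that("engineered clusters reproduce support totals and orientation labels", {
  ann <- tiny_annotation()
  params <- calling_params()
  ev <- dplyr::bind_rows(
    ev_cluster(5421, "MuDR", "TE_MUDR1", p = 4, i = 11,
               individual_id = "a"),
    ev_cluster(116237, "Copia", "TE_COP1", p = 47, i = 10,
               individual_id = "a"),
    ev_cluster(42355, "Helitron", "TE_HEL1", p = 10, i = 1,
               individual_id = "a"))
  calls <- tidy(call_te_events(ev, ann, params))

  mudr <- calls[calls$item == "MuDR", ]
  expect_equal(mudr$read_pair_support, 15L)
  expect_equal(mudr$orientation, "inverse")
  expect_equal(mudr$p_pairs, 4L)
  expect_equal(mudr$i_pairs, 11L)
  expect_equal(mudr$novelty, "new")
  expect_equal(mudr$len, 7679L)
  expect_equal(mudr$event_type_ref, "TE+DNA/MuDR/DNA/MuDR")

  copia <- calls[calls$item == "Copia", ]
  expect_equal(copia$read_pair_support, 57L)
  expect_equal(copia$orientation, "parallel")

  heli <- calls[calls$item == "Helitron", ]
  expect_equal(heli$orientation, "parallel")
  expect_equal(heli$read_pair_support, 11L)

  ## every new event keeps p + i = support
  nn <- calls[calls$novelty == "new" & calls$orientation != "uncertain", ]
  expect_equal(nn$p_pairs + nn$i_pairs, nn$read_pair_support)
})

test_that("orientation ties, unknown source strands and old events are uncertain", {
  ann <- tiny_annotation()
  params <- calling_params()
  tie <- ev_cluster(9000, "Gypsy", "TE_GYP1", p = 5, i = 5)
  expect_equal(classify_orientation(tie)$orientation, "uncertain")
  expect_equal(classify_orientation(tie)$p_pairs, 5L)

  unk <- ev_cluster(9000, "Gypsy", "TE_GYP1", p = 6, i = 1, te_strand = "*")
  expect_equal(classify_orientation(unk)$orientation, "uncertain")

  ## an event right on a reference copy of its own item is old + uncertain
  old_ev <- ev_cluster(1000500, "MuDR", "TE_MUDR1", p = 9, i = 0,
                       chrom = "chr9")
  calls <- tidy(call_te_events(old_ev, ann, params))
  expect_equal(calls$novelty, "old")
  expect_equal(calls$orientation, "uncertain")
  expect_true(is.na(calls$p_pairs) && is.na(calls$i_pairs))
})

test_that("novelty compares item loci at the active level, within the window", {
  ann <- tiny_annotation()
  params <- calling_params()  # window 600
  ## inside an annotated Copia copy -> old
  expect_equal(classify_novelty("chr9", 2000100L, "Copia", ann, params), "old")
  ## just beyond the window from any Copia -> new
  expect_equal(classify_novelty("chr9", 2003541 + 1e5, "Copia", ann, params),
               "new")
  ## within the window of the end -> old
  expect_equal(classify_novelty("chr9", 2002940 + 600, "Copia", ann, params),
               "old")
  expect_equal(classify_novelty("chr9", 2002940 + 601, "Copia", ann, params),
               "new")
  ## inside a Gypsy copy but called Copia -> new (item mismatch)
  expect_equal(classify_novelty("chr9", 4000100L, "Copia", ann, params), "new")
})

test_that("event type strings repeat the class/superfamily path", {
  expect_equal(format_event_type("LTR", "Copia"), "TE+LTR/Copia/LTR/Copia")
  expect_equal(format_event_type("RC", "Helitron"),
               "TE+RC/Helitron/RC/Helitron")
  expect_equal(format_event_type("DNA", "HAT"), "TE+DNA/HAT/DNA/HAT")
})

test_that("clusters below min_support are dropped; tie on source element is lexicographic", {
  ann <- tiny_annotation()
  params <- calling_params(min_support = 3)
  small <- ev_cluster(7000, "Copia", "TE_COP1", p = 1)
  expect_equal(nrow(tidy(call_te_events(small, ann, params))), 0)

  ## equal support from two source elements: smallest te_id supplies len
  tie <- dplyr::bind_rows(
    ev_cluster(7000, "Copia", "TE_COP2", p = 2),
    ev_cluster(7010, "Copia", "TE_COP1", p = 2))
  calls <- tidy(call_te_events(tie, ann, params))
  expect_equal(calls$te_id, "TE_COP1")
  expect_equal(calls$len, 2941L)
})

test_that("calling is deterministic and loc is the floored median anchor", {
  ann <- tiny_annotation()
  params <- calling_params()
  ev <- dplyr::bind_rows(
    ev_cluster(5000, "Copia", "TE_COP1", p = 5, i = 2, individual_id = "b"),
    ev_cluster(40000, "Gypsy", "TE_GYP1", p = 0, i = 4, individual_id = "a"))
  c1 <- call_te_events(ev, ann, params)
  c2 <- call_te_events(ev[sample(nrow(ev)), ], ann, params)
  expect_identical(c1$events, c2$events)
  expect_identical(c1$presence, c2$presence)
  gy <- c1$events[c1$events$item == "Gypsy", ]
  anchors <- sort(ev$anchor_pos[ev$item == "Gypsy"])
  expect_equal(gy$loc, as.integer(floor(median(anchors))))
})
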