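# Annotation matrix, activity filter, and the stage-count cascade.

test_that("annotation matrix marks any-overlap cells and keeps input order", {
  regions <- genomic_intervals("chr1", c(0, 100, 200), c(50, 150, 250),
                               c("R1", "R2", "R3"))
  h3k <- chromatin_track("H3K27ac", "histone",
                         genomic_intervals("chr1", 10, 40, "p1"))
  tf <- chromatin_track("FOX_TF", "tf",
                        genomic_intervals("chr1", c(120, 210), c(160, 260),
                                          c("p2", "p3")))
  tracks <- dplyr::bind_rows(h3k, tf)
  am <- build_annotation_matrix(regions, tracks)
  expect_equal(names(am), c("region_id", "H3K27ac", "FOX_TF"))
  expect_equal(am$region_id, c("R1", "R2", "R3"))
  expect_equal(am$H3K27ac, c(TRUE, FALSE, FALSE))
  expect_equal(am$FOX_TF, c(FALSE, TRUE, TRUE))

  # zero tracks -> zero annotation columns
  none <- build_annotation_matrix(regions, h3k[0, ])
  expect_equal(names(none), "region_id")

  expect_error(
    build_annotation_matrix(regions, dplyr::bind_rows(h3k, h3k)),
    "unique"
  )
})

test_that("annotation matrix equals the brute-force overlap oracle", {
  set.seed(21)
  regions <- random_intervals(50, prefix = "G")
  tracks <- dplyr::bind_rows(lapply(1:5, function(t) {
    chromatin_track(sprintf("trk%d", t), "other",
                    random_intervals(8, prefix = sprintf("t%d_", t)))
  }))
  am <- build_annotation_matrix(regions, tracks)
  for (t in seq_len(nrow(tracks))) {
    peaks <- tracks$intervals[[t]]
    want <- vapply(seq_len(nrow(regions)), function(i) {
      any(vapply(seq_len(nrow(peaks)), function(j) {
        oracle_overlap(regions$chrom[i], regions$start[i], regions$end[i],
                       peaks$chrom[j], peaks$start[j], peaks$end[j])
      }, logical(1)))
    }, logical(1))
    expect_equal(am[[tracks$name[t]]], want)
  }
})

test_that("call_active keeps exactly the members under activity peaks", {
  members <- genomic_intervals("chr1", seq(0, 400, 100),
                               seq(0, 400, 100) + 50,
                               sprintf("M%d", 1:5))
  peaks <- genomic_intervals("chr1", c(20, 320), c(60, 380), c("p1", "p2"))
  act <- chromatin_track("H3K27ac", "histone", peaks)
  got <- call_active(members, act)
  expect_setequal(got$region_id, c("M1", "M4"))

  empty_act <- chromatin_track(
    "H3K27ac", "histone",
    genomic_intervals(character(), integer(), integer(), character())
  )
  expect_equal(nrow(call_active(members, empty_act)), 0)

  tf <- chromatin_track("AR", "tf", peaks)
  expect_error(call_active(members, tf), "histone")
})

test_that("mutated percentage uses half-up rounding to one decimal", {
  expect_equal(mutated_percent(6, 33), 18.2)
  expect_equal(mutated_percent(0, 33), 0)
  expect_equal(mutated_percent(1, 16), 6.3)   # 6.25 rounds half-up
  expect_true(is.na(mutated_percent(0, 0)))
})

test_that("cascade on the seed-1 fixture reproduces its truth manifest", {
  st <- simulate_plexus_study(seed = 1)
  rep <- run_cascade(st$regions, st$tad, st$matrix, st$truth$anchor_id,
                     st$activity_track, st$variants)
  expect_equal(rep$n_dhs_in_window, st$truth$n_dhs_in_window)
  expect_equal(rep$n_plexus_members, st$truth$n_members)
  expect_equal(rep$n_active, st$truth$n_active)
  expect_equal(rep$n_mutated, st$truth$n_mutated)
  expect_equal(rep$n_variants, st$truth$n_variants)
  expect_equal(rep$n_tumors, st$truth$n_tumors)
  # the fixture's planted layer: 12 members, 8 marked, 3 mutated,
  # 5 SNVs from 4 tumors
  expect_equal(glance(rep)$n_plexus_members, 12)
  expect_equal(glance(rep)$n_active, 8)
  expect_equal(glance(rep)$n_mutated, 3)
  expect_equal(glance(rep)$n_variants, 5)
  expect_equal(glance(rep)$n_tumors, 4)
})

test_that("cascade counts are monotone and the fraction is self-consistent", {
  for (seed in c(2, 3, 4)) {
    st <- simulate_plexus_study(seed = seed)
    rep <- run_cascade(st$regions, st$tad, st$matrix, st$truth$anchor_id,
                       st$activity_track, st$variants)
    expect_gte(rep$n_dhs_in_window, rep$n_plexus_members)
    expect_gte(rep$n_plexus_members, rep$n_active)
    expect_gte(rep$n_active, rep$n_mutated)
    expect_gte(rep$n_variants, rep$n_mutated)
    expect_equal(rep$fraction_mutated, rep$n_mutated / rep$n_active)
    txt <- format(rep)
    expect_match(txt[length(txt)],
                 sprintf("%.1f%%", mutated_percent(rep$n_mutated,
                                                   rep$n_active)),
                 fixed = TRUE)
  }
})

test_that("cascade without variants reports zero mutated and 0% fraction", {
  st <- simulate_plexus_study(seed = 6)
  no_vars <- st$variants[0, ]
  rep <- run_cascade(st$regions, st$tad, st$matrix, st$truth$anchor_id,
                     st$activity_track, no_vars)
  expect_equal(rep$n_mutated, 0)
  expect_equal(rep$n_variants, 0)
  expect_equal(rep$fraction_mutated, 0)
})

test_that("cascade with no active members reports a not-applicable fraction", {
  st <- simulate_plexus_study(seed = 7)
  empty_act <- chromatin_track(
    "H3K27ac", "histone",
    genomic_intervals(character(), integer(), integer(), character())
  )
  rep <- run_cascade(st$regions, st$tad, st$matrix, st$truth$anchor_id,
                     empty_act, st$variants)
  expect_equal(rep$n_active, 0)
  expect_true(is.na(rep$fraction_mutated))
  expect_match(paste(format(rep), collapse = "\n"), "n/a")
})
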