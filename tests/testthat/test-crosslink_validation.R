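test_that("identification filters drop high-E-value, low-repeat and self links", {
  tab <- rbind(
    xl_row(100, 250, count = 3),
    xl_row(100, 250, count = 4),            # duplicate pair: merge to 7
    xl_row(250, 100, count = 2),            # reversed orientation: same pair
    xl_row(10, 20, e_value = 1e-3),         # fails E-value filter
    xl_row(30, 40, n_repeats = 1L),         # fails repeat filter
    xl_row(50, 50)                          # self link
  )
  expect_warning(recs <- parse_crosslinks(tab), "self-link")
  expect_equal(nrow(recs), 1L)
  expect_equal(recs$pos_a, 100L)
  expect_equal(recs$pos_b, 250L)
  expect_equal(recs$spectral_count, 9L)
  # boundary: E-value filter is strict less-than
  expect_equal(nrow(suppressWarnings(
    parse_crosslinks(xl_row(1, 2, e_value = 1e-4)))), 0L)
})

test_that("column dialects are configurable and schema errors are informative", {
  tab <- data.frame(Pos1 = 5L, Pos2 = 9L, CSMs = 3L, Evalue = 1e-6)
  recs <- parse_crosslinks(tab, cols = c(pos_a = "Pos1", pos_b = "Pos2",
                                         spectral_count = "CSMs",
                                         e_value = "Evalue"))
  expect_equal(recs$spectral_count, 3L)
  expect_equal(recs$res_a, "K")
  expect_error(parse_crosslinks(data.frame(a = 1)), "missing required column")
})

test_that("crosslinks map as C-beta distances with strict 30 A classification", {
  m12 <- two_lys_model(12.0)
  rec <- parse_crosslinks(xl_row(100, 250, count = 2))
  mp <- map_crosslink(m12, rec[1, ])
  expect_equal(mp$distance, 12.0)
  expect_equal(mp$status, "satisfied")

  # exactly at the cutoff: violated (satisfied requires strictly < 30)
  m30 <- two_lys_model(30.0)
  expect_equal(map_crosslink(m30, rec[1, ])$status, "violated")
  m29 <- two_lys_model(29.999)
  expect_equal(map_crosslink(m29, rec[1, ])$status, "satisfied")
})

test_that("distance is symmetric in the link orientation", {
  m <- two_lys_model(17.3)
  ab <- map_crosslink(m, xl_row(100, 250))
  ba <- map_crosslink(m, xl_row(250, 100))
  expect_equal(ab$distance, ba$distance)
  expect_equal(ab$status, ba$status)
})

test_that("links into deleted or unbuilt regions are unmapped", {
  m <- two_lys_model(12, resnos = c(100L, 250L))
  # full-length position inside the IP4P loop deletion: no construct image
  nm <- prex1_numbering("d1119_1211")
  mp <- map_crosslink(m, xl_row(100, 1150), nm = nm)
  expect_equal(mp$status, "unmapped")
  expect_true(is.na(mp$distance))
  # residue simply not built in the model
  mp2 <- map_crosslink(m, xl_row(100, 999))
  expect_equal(mp2$status, "unmapped")
  # non-lysine chemistry is unmapped, not guessed
  mp3 <- map_crosslink(m, xl_row(100, 250, res_b = "S"))
  expect_equal(mp3$status, "unmapped")
})

test_that("lysine identity mismatches raise a numbering-map error", {
  m <- toy_ca_model(5)  # ALA residues
  expect_error(map_crosslink(m, xl_row(1, 3)), "not lysine")
  expect_equal(map_crosslink(m, xl_row(1, 3), check_identity = FALSE)$status,
               "unmapped")  # no CB atoms to measure
})

test_that("multi-chain copies resolve to the minimum distance", {
  at <- do.call(rbind, lapply(list(c("A", 0), c("B", 40)), function(ch) {
    data.frame(elety = c("CA", "CB", "CA", "CB"), resid = "LYS",
               chain = ch[1], resno = c(7L, 7L, 9L, 9L),
               x = as.numeric(ch[2]) + c(0, 0, 0, 10), y = c(1, 0, 1, 0),
               z = 0, elesy = "C", stringsAsFactors = FALSE)
  }))
  m <- structure_model(at, label = "dimer")
  mp <- map_crosslink(m, xl_row(7, 9))
  expect_equal(mp$distance, 10)  # within-chain pairing, not 30 or 50
})

test_that("model FDR equals brute-force frequency summation on small sets", {
  # spec arithmetic example: counts 10+5 satisfied, 5 violated -> 0.25
  mk_mapped <- function(status, counts, model = "toy") {
    structure(data.frame(model = model,
                         pos_a = seq_along(status) * 2L,
                         pos_b = seq_along(status) * 2L + 100L,
                         spectral_count = counts, distance = 10,
                         status = status, stringsAsFactors = FALSE),
              class = c("mapped_crosslinks", "data.frame"))
  }
  r <- model_fdr(mk_mapped(c("satisfied", "satisfied", "violated"),
                           c(10L, 5L, 5L)))
  expect_equal(r$fdr, 0.25)
  expect_equal(model_fdr(mk_mapped(rep("satisfied", 4), rep(2L, 4)))$fdr, 0)

  # random toy sets of <= 12 links vs the independent brute-force oracle
  set.seed(42)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    status <- sample(c("satisfied", "violated", "unmapped"), n,
                     replace = TRUE, prob = c(0.6, 0.3, 0.1))
    if (all(status == "unmapped")) status[1] <- "satisfied"
    counts <- sample(1:20, n, replace = TRUE)
    mp <- mk_mapped(status, counts)
    expect_identical(model_fdr(mp)$fdr, brute_force_fdr(status, counts))
    # invariance under uniform positive integer scaling of counts
    mp2 <- mp; mp2$spectral_count <- mp2$spectral_count * 7L
    expect_equal(model_fdr(mp2)$fdr, model_fdr(mp)$fdr)
    # monotonicity: dropping a violated link never increases the FDR
    iv <- which(status == "violated")
    if (length(iv) > 0 && sum(status != "unmapped") > 1) {
      expect_lte(model_fdr(mp[-iv[1], ])$fdr, model_fdr(mp)$fdr)
    }
    is <- which(status == "satisfied")
    if (length(is) > 0 && sum(status != "unmapped") > 1 &&
        length(iv) > 0) {
      expect_gte(model_fdr(mp[-is[1], ])$fdr, model_fdr(mp)$fdr)
    }
  }
})

test_that("unmapped links are excluded from the default denominator", {
  mp <- structure(data.frame(
    model = "m", pos_a = c(1L, 3L, 5L), pos_b = c(2L, 4L, 6L),
    spectral_count = c(4L, 4L, 8L), distance = c(10, 40, NA),
    status = c("satisfied", "violated", "unmapped"),
    stringsAsFactors = FALSE), class = c("mapped_crosslinks", "data.frame"))
  expect_equal(model_fdr(mp, "mapped")$fdr, 0.5)
  expect_equal(model_fdr(mp, "all_observed")$fdr, 0.25)
  expect_equal(model_fdr(mp)$n_unmapped, 1L)
  all_un <- mp; all_un$status <- "unmapped"
  expect_error(model_fdr(all_un), "no mappable")
})

test_that("conformer comparison ranks the sampled conformation lower in FDR", {
  closed <- make_helix(60, res_name = "LYS", label = "closed")
  # open conformer: straighten nothing, just stretch the chain 3x so that
  # most restraints sampled on the closed model are violated
  open <- closed
  open$atoms$z <- open$atoms$z * 4
  open$label <- "open"
  tab <- simulate_crosslinks(closed, n_links = 24, violated_fraction = 0,
                             seed = 7)
  recs <- parse_crosslinks(tab)
  mapped <- list(closed = map_crosslinks(closed, recs),
                 open = map_crosslinks(open, recs))
  cmp <- compare_conformers(mapped)
  expect_equal(cmp$model, c("closed", "open"))
  expect_lt(cmp$fdr[cmp$model == "closed"], cmp$fdr[cmp$model == "open"])
  sm <- attr(cmp, "status_matrix")
  expect_equal(dim(sm), c(nrow(recs), 2L))

  # identical model under two labels gives identical rows
  same <- compare_conformers(list(a = mapped$closed, b = mapped$closed))
  expect_equal(same$fdr[1], same$fdr[2])
  expect_equal(unname(unlist(same[1, -1])), unname(unlist(same[2, -1])))
  expect_error(compare_conformers(setNames(mapped, c("x", "x"))), "unique")
})

test_that("circos export carries positions, counts and status colors", {
  m <- two_lys_model(12)
  mp <- map_crosslinks(m, parse_crosslinks(xl_row(100, 250, count = 5)))
  ci <- circos_links(mp)
  expect_equal(ci$start, 100L)
  expect_equal(ci$end, 250L)
  expect_equal(ci$value, 5L)
  expect_equal(ci$color, "blue")
})
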