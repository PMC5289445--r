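test_that("clade proportions normalize S/H ratios to 100%", {
  q <- tibble::tibble(sample_id = "s1", clade = "C", sh_ratio = 0.4)
  expect_equal(clade_proportions(q)$proportion, 100)

  q2 <- tibble::tibble(sample_id = "s2", clade = c("C", "D"),
                       sh_ratio = c(3, 1))
  p2 <- clade_proportions(q2)
  expect_equal(setNames(p2$proportion, p2$clade), c(C = 75, D = 25))

  # the printed Li-02 C/D split arises from ratios in that proportion
  q3 <- tibble::tibble(sample_id = "Li-02", clade = c("C", "D"),
                       sh_ratio = c(0.5107, 0.4893) * 7.3)
  p3 <- clade_proportions(q3)
  expect_equal(setNames(p3$proportion, p3$clade),
               c(C = 51.07, D = 48.93), tolerance = 1e-9)
})

test_that("proportions are invariant to rescaling a sample's ratios", {
  q <- tibble::tibble(sample_id = "s1", clade = c("A", "C", "D"),
                      sh_ratio = c(0.02, 1.3, 0.6))
  scaled <- dplyr::mutate(q, sh_ratio = sh_ratio * 1e4)
  expect_equal(clade_proportions(q)$proportion,
               clade_proportions(scaled)$proportion, tolerance = 1e-12)
})

test_that("samples with no detected clade are dropped with a warning", {
  q <- tibble::tibble(sample_id = c("s1", "s2"), clade = "C",
                      sh_ratio = c(NA_real_, 1))
  expect_warning(p <- clade_proportions(q), "no detected clade")
  expect_equal(p$sample_id, "s2")
  expect_equal(attr(p, "undetected"), "s1")
})

test_that("the 5% dominance cut is boundary-inclusive for background", {
  p <- tibble::tibble(
    sample_id = "Li-04", clade = c("A", "D"),
    proportion = c(1.5718, 98.4282)
  )
  cls <- classify_dominant_background(p)
  expect_equal(setNames(cls$class, cls$clade),
               c(A = "background", D = "dominant"))

  edge <- tibble::tibble(sample_id = "x", clade = c("C", "D"),
                         proportion = c(5, 95))
  ce <- classify_dominant_background(edge)
  expect_equal(ce$class, c("background", "dominant"))
  expect_true(ce$near_boundary[1])   # exactly at the cut: flagged
  expect_false(ce$near_boundary[2])

  mono <- tibble::tibble(sample_id = "y", clade = "C", proportion = 100)
  expect_equal(classify_dominant_background(mono)$class, "dominant")
})

test_that("classification is invariant to clade ordering", {
  p <- tibble::tibble(sample_id = "s", clade = c("D", "A", "C"),
                      proportion = c(90, 4, 6))
  shuffled <- p[c(2, 3, 1), ]
  a <- classify_dominant_background(p) |> dplyr::arrange(clade)
  b <- classify_dominant_background(shuffled) |> dplyr::arrange(clade)
  expect_equal(a, b)
})

test_that("pattern labels are canonical alphabetical strings", {
  expect_equal(pattern_label("C"), "C")
  expect_equal(pattern_label(c("D", "C", "A")), "ACD")
  expect_equal(pattern_label(c("D", "B", "C")), "BCD")
  expect_equal(pattern_label(c("C", "C", "A")), "AC")  # duplicates collapse
  expect_error(pattern_label(character()))
})

test_that("pattern enumeration covers every non-empty subset once", {
  p4 <- enumerate_patterns(c("A", "B", "C", "D"))
  expect_length(p4, 15)
  expect_equal(anyDuplicated(p4), 0)

  expect_equal(enumerate_patterns("A"), "A")
  expect_length(enumerate_patterns(c("A", "B", "C")), 7)

  # brute-force oracle: presence/absence bitmasks over k clades
  clades <- c("A", "B", "C", "E")
  brute <- apply(expand.grid(rep(list(c(FALSE, TRUE)), 4)), 1, function(keep) {
    if (!any(keep)) NA_character_ else paste(clades[keep], collapse = "")
  })
  brute <- sort(brute[!is.na(brute)])
  expect_setequal(enumerate_patterns(clades), brute)

  # every observable pattern is a member of the theoretical set
  for (i in 1:10) {
    sub <- sample(clades, sample(1:4, 1))
    expect_true(pattern_label(sub) %in% enumerate_patterns(clades))
  }
})

make_profiles <- function(patterns_by_species) {
  purrr::imap_dfr(patterns_by_species, function(patterns, sp) {
    purrr::imap_dfr(patterns, function(pat, i) {
      clades <- strsplit(pat, "")[[1]]
      k <- length(clades)
      tibble::tibble(
        sample_id = sprintf("%s_%02d", sp, i), species = sp, site = "Va",
        clade = clades,
        proportion = c(100 - 2 * (k - 1), rep(2, k - 1)),
        class = c("dominant", rep("background", k - 1)),
        near_boundary = FALSE, pattern = pat
      )
    })
  })
}

test_that("species summaries reproduce the printed tallies under the rounding policy", {
  profs <- make_profiles(list(
    damicornis_like = c(rep("D", 24), "BCD", "ABC", "CD"),   # 24/27 mono
    rus_like = c(rep("C", 18), "AC", "AC", "CD")             # 18/21 mono
  ))
  s <- species_summary(profs)
  mono <- dplyr::distinct(s, species, mono_clade_pct, multi_clade_pct)
  dam <- dplyr::filter(mono, species == "damicornis_like")
  expect_equal(round_percent(dam$mono_clade_pct, "summary"), 89)
  rus <- dplyr::filter(mono, species == "rus_like")
  expect_equal(round_percent(rus$mono_clade_pct, "group"), 85.7)
  expect_equal(dam$mono_clade_pct + dam$multi_clade_pct, 100)
  # counts sum to the species sample size
  expect_equal(
    sum(dplyr::filter(s, species == "damicornis_like")$n), 27
  )
})

test_that("pattern-group percentages use one-decimal rounding", {
  profs <- make_profiles(list(
    cytherea_like = c(rep("AD", 9), "ACD", "ACD", rep("A", 3), "AC", "CD"),
    pulchra_like = c("AC", "AC", "AC", "ACD", "A", "AD")
  ))
  g1 <- pattern_group_pct(profs, "cytherea_like", c("AD", "ACD"))
  expect_equal(g1$n_match, 11)
  expect_equal(g1$pct_rounded, 68.8)
  g2 <- pattern_group_pct(profs, "pulchra_like", c("AC", "ACD"))
  expect_equal(g2$n_match, 4)
  expect_equal(g2$pct_rounded, 66.7)
  expect_error(pattern_group_pct(profs, "nope", "A"), "Unknown species")
})

test_that("all-mono profiles summarise to 100% mono, 0% multi", {
  profs <- make_profiles(list(x = rep("C", 5)))
  s <- species_summary(profs)
  expect_equal(unique(s$mono_clade_pct), 100)
  expect_equal(unique(s$multi_clade_pct), 0)
})

test_that("community_profiles chains proportions, classes and patterns", {
  q <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), c(2, 1)),
    clade = c("C", "D", "C"),
    sh_ratio = c(0.9, 0.03, 1.2)
  )
  meta <- tibble::tibble(sample_id = c("s1", "s2"),
                         species = "X", site = "Li")
  prof <- community_profiles(q, metadata = meta)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$pattern[prof$sample_id == "s1"], c("CD", "CD"))
  d <- dplyr::filter(prof, sample_id == "s1", clade == "D")
  expect_equal(d$class, "background")
  expect_equal(d$proportion, 100 * 0.03 / 0.93, tolerance = 1e-12)
  expect_true(all(prof$species == "X"))
})
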