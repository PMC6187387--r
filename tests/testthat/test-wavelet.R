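test_that("filter pairs satisfy the orthogonal-wavelet invariants", {
  for (name in c("haar", "db2")) {
    f <- wavelet_filters(name)
    L <- length(f$h)
    expect_identical(length(f$g), L)
    expect_identical(L %% 2L, 0L)
    expect_equal(sum(f$h), sqrt(2), tolerance = 1e-12)
    # quadrature-mirror relation g(k) = (-1)^k h(2N-1-k), 0-based
    k <- seq_len(L) - 1L
    expect_equal(f$g, (-1)^k * f$h[L - k], tolerance = 1e-12)
  }
})

test_that("Haar splits a constant signal into scaled approx and zero detail", {
  s <- packet_step(rep(3, 8), wavelet_filters("haar"))
  expect_equal(s$approx, rep(3 * sqrt(2), 4), tolerance = 1e-12)
  expect_equal(s$detail, rep(0, 4), tolerance = 1e-12)
})

test_that("db2 step reproduces frozen reference periodization coefficients", {
  # values computed once with an established wavelet library in
  # periodization mode
  s <- packet_step(as.numeric(1:8), wavelet_filters("db2"))
  expect_equal(s$approx,
               c(4.760278777324327, 3.7250025969142437,
                 6.553429721660434, 10.417133026816707), tolerance = 1e-12)
  expect_equal(s$detail,
               c(-1.035276180410083, 0, 0, 3.8637033051562737),
               tolerance = 1e-12)
})

test_that("level-2 packet tree matches frozen reference coefficients", {
  x <- c(0.547912, -0.122243, 0.717196, 0.394736, -0.811645, 0.951245,
         0.522279, 0.572129, -0.743773, -0.099228, -0.258404, 0.85353,
         0.28773, 0.645523, -0.113172, -0.545523)
  frozen <- list(
    haar = list(
      "2.0" = c(0.7688005, 0.617004, -0.1239375, 0.137279),
      "2.1" = c(-0.3431315, -0.477404, -0.7190635, 0.795974),
      "2.2" = c(0.4963075, -0.90637, -0.8782395, 0.037279),
      "2.3" = c(0.1738475, -0.85652, 0.2336945, -0.395072)),
    db2 = list(
      "2.0" = c(0.282963721345573, 0.362566315613191,
                0.131585262746772, 0.622030700294463),
      "2.1" = c(0.760028729105793, 1.08096784573743,
                -0.554336530985335, -0.183878801793629),
      "2.2" = c(-0.753137709524748, 0.959443782764041,
                0.491560286454126, 0.553156640306582),
      "2.3" = c(0.370300903797378, 0.209145754735071,
                0.230032899226668, -0.587506416869913)))
  for (name in names(frozen)) {
    tree <- wp_decompose(x, wavelet_filters(name), levels = 2L)
    for (key in names(frozen[[name]])) {
      lev <- as.integer(strsplit(key, ".", fixed = TRUE)[[1L]][1L])
      idx <- as.integer(strsplit(key, ".", fixed = TRUE)[[1L]][2L])
      expect_equal(wp_node(tree, lev, idx), frozen[[name]][[key]],
                   tolerance = 1e-9)
    }
  }
})

test_that("every node matches the brute-force periodized oracle", {
  set.seed(101)
  lengths <- sort(sample(8:1024, 100L, replace = TRUE))
  for (name in c("haar", "db2")) {
    f <- wavelet_filters(name)
    for (n in lengths) {
      x <- rnorm(n)
      levels <- min(3L, floor(log2(n)))
      tree <- wp_decompose(x, f, levels)
      oracle <- oracle_packet_tree(x, f, levels)
      for (key in names(oracle)) {
        got <- tree$nodes[[key]]$coefficients
        ref <- oracle[[key]]
        expect_lt(max(abs(got - ref)) / max(1e-12, max(abs(ref))), 1e-8)
      }
    }
  }
})

test_that("each packet step conserves energy (Parseval)", {
  set.seed(7)
  for (name in c("haar", "db2")) {
    f <- wavelet_filters(name)
    for (n in c(8L, 64L, 1000L)) {
      x <- rnorm(n)
      s <- packet_step(x, f)
      expect_equal(sum(s$approx^2) + sum(s$detail^2), sum(x^2),
                   tolerance = 1e-9)
    }
  }
})

test_that("a single packet step is invertible", {
  set.seed(8)
  for (name in c("haar", "db2")) {
    f <- wavelet_filters(name)
    x <- rnorm(64)
    s <- packet_step(x, f)
    expect_equal(ridergait:::.packet_step_inverse(s$approx, s$detail, f), x,
                 tolerance = 1e-9)
  }
})

test_that("node lengths follow ceil(n / 2^L)", {
  f <- wavelet_filters("db2")
  for (n in c(8L, 13L, 50L, 49L, 100L, 1021L)) {
    x <- rnorm(n)
    tree <- wp_decompose(x, f, 3L)
    for (L in 0:3) {
      expect_length(wp_node(tree, L, 0L), ceiling(n / 2^L))
    }
  }
})

test_that("the 49,000-sample approximation path compresses to 12,250 then 6,125", {
  x <- sin(2 * pi * seq_len(49000) / 120) + 0.1 * cos(seq_len(49000))
  tree <- wp_decompose(x, wavelet_filters("db2"), levels = 3L)
  expect_length(wp_node(tree, 2L, 0L), 12250L)
  expect_length(wp_node(tree, 3L, 0L), 6125L)
  expect_identical(wp_node(tree, 0L, 0L), x)  # root is the signal itself
})

test_that("tree bookkeeping and errors behave", {
  x <- rnorm(16)
  tree <- wp_decompose(x, wavelet_filters("haar"), 3L)
  expect_length(tree$nodes, 15L)  # 1 + 2 + 4 + 8
  expect_error(wp_node(tree, 4L, 0L), "not in tree")
  expect_error(wp_decompose(numeric(0)), "empty signal")
  expect_error(wp_decompose(rnorm(4), levels = 3L), "too many levels")
  expect_error(packet_step(numeric(0)), "empty signal")
  s <- wp_decompose(c(1, 2), wavelet_filters("haar"), 1L)
  expect_length(wp_node(s, 1L, 0L), 1L)
  expect_length(wp_node(s, 1L, 1L), 1L)
})

test_that("compress_recording halves lengths per level and works channel-wise", {
  spec <- default_gait_specs()$rising_trot
  rec <- generate_recording(spec, 480L, seed = 2L)
  f <- wavelet_filters("db2")
  comp <- compress_recording(rec, f, level = 2L)
  expect_equal(dim(comp), c(120L, 8L))
  expect_identical(colnames(comp), gait_channels())
  # identity at level 0
  expect_identical(compress_recording(rec, f, level = 0L), rec$values)
  # per-channel independence
  for (ch in c(1L, 5L)) {
    tree <- wp_decompose(rec$values[, ch], f, 2L)
    expect_equal(comp[, ch], wp_node(tree, 2L, 0L), tolerance = 1e-12)
  }
})
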