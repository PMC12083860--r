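leak_cell <- function(g = 1, E = -80)
  cell_spec(channels = list(), g_leak = g, E_leak = E, noise_sd = 0,
            cap_transient_amp = 0)

test_that("leak-only sweep matches the Ohmic closed form", {
  p <- default_protocol()
  tr <- simulate_sweep(leak_cell(), p, 4, noise = FALSE)  # step to +20 mV
  t <- time_axis(p)
  expect_equal(unique(tr[t >= 50 & t < 350]), 100)  # 1 nS * (20 - (-80)) mV
  expect_equal(unique(tr[t < 50]), 0)
})

test_that("plateau current matches the gating steady state", {
  # single non-inactivating channel at +40 mV: g * minf^p * (V - E)
  ch <- channel_model("K", g_max = 10, E_rev = -90, p = 1, q = 0,
                      m_vhalf = -10, m_slope = 10, tau_m = 5)
  cell <- cell_spec(channels = list(ch), g_leak = 0, noise_sd = 0,
                    cap_transient_amp = 0)
  tr <- simulate_sweep(cell, default_protocol(), 5, noise = FALSE)
  expected <- 10 * (1 / (1 + exp(-5))) * 130   # = 1291.3 pA
  plateau <- tr[3400]  # 340 ms, late in the step
  expect_lt(abs(plateau - expected) / expected, 0.005)
})

test_that("the sodium preset produces a fast transient decaying within ~15 ms", {
  b <- patchkin:::base_channels()
  cell <- cell_spec(channels = b["na"], g_leak = 0, noise_sd = 0,
                    cap_transient_amp = 0)
  p <- default_protocol()
  tr <- simulate_sweep(cell, p, 4, noise = FALSE)  # +20 mV
  t <- time_axis(p)
  stim <- which(t >= p$onset & t < p$offset)
  ipk <- stim[which.min(tr[stim])]
  expect_lt(t[ipk] - p$onset, 15)                 # peak inside the first 15 ms
  peak <- tr[ipk]
  after <- stim[t[stim] > t[ipk]]
  t10 <- t[after[which(tr[after] >= 0.1 * peak)[1]]] - t[ipk]
  expect_gt(t10, 5)                               # peak-to-10% decay ~ 15 ms
  expect_lt(t10, 25)
})

test_that("gating variables stay in [0, 1] and channel current is linear in g_max", {
  set.seed(5)
  p <- default_protocol()
  for (i in 1:20) {
    m <- patchkin:::gate_trajectory(p, runif(1, -120, 60), runif(1, -80, 20),
                                    sample(c(-1, 1), 1) * runif(1, 3, 15),
                                    runif(1, 0.5, 60))
    expect_true(all(m >= 0 & m <= 1))
  }
  ch <- channel_model("K", g_max = 5, E_rev = -90, p = 2, q = 1,
                      m_vhalf = -20, m_slope = 9, tau_m = 4,
                      h_vhalf = -50, h_slope = -6, tau_h = 30)
  cell1 <- cell_spec(channels = list(ch), g_leak = 0, noise_sd = 0,
                     cap_transient_amp = 0)
  ch2 <- ch; ch2$g_max <- 10
  cell2 <- cell1; cell2$channels <- list(ch2)
  tr1 <- simulate_sweep(cell1, p, 5, noise = FALSE)
  tr2 <- simulate_sweep(cell2, p, 5, noise = FALSE)
  expect_equal(tr2, 2 * tr1, tolerance = 1e-12)
})

test_that("refining the sampling grid leaves noise-free samples unchanged", {
  # gating is solved in closed form per voltage segment, so a 10x finer grid
  # must reproduce the coarse samples exactly (well inside the 0.1% bound)
  b <- patchkin:::base_channels()
  cell <- cell_spec(channels = b[c("na", "kdr")], g_leak = 1, noise_sd = 0)
  coarse <- simulate_sweep(cell, default_protocol(1), 5, noise = FALSE)
  fine <- simulate_sweep(cell, default_protocol(10), 5, noise = FALSE)
  common <- fine[seq(1, length(fine), by = 10)]
  denom <- pmax(abs(coarse), 1)
  expect_lt(max(abs(coarse - common) / denom), 1e-3)
})

test_that("seeded generation is reproducible and labels are validated", {
  a <- generate_recording("category_I", default_protocol(1), seed = 42)
  b <- generate_recording("category_I", default_protocol(1), seed = 42)
  expect_identical(a$traces, b$traces)
  c_ <- generate_recording("category_I", default_protocol(1), seed = 43)
  expect_false(identical(a$traces, c_$traces))
  expect_error(generate_recording("category_VII"), "unknown label")
})

test_that("category II outward current is unsustainable", {
  # module definition of the phenotype: for steps >= 0 mV, the mean evoked
  # current over the last 50 ms of the stimulus is < 50% of the sweep's
  # outward peak
  p <- default_protocol(1)
  t <- time_axis(p)
  base <- t < p$onset
  stim <- t >= p$onset & t < p$offset
  late <- t >= (p$offset - 50) & t < p$offset
  for (seed in 1:50) {
    rec <- generate_recording("category_II", p, seed = seed)
    for (i in which(rec$protocol$steps >= 0)) {
      x <- rec$traces[i, ]
      b <- mean(x[base])
      expect_lt(mean(x[late]) - b, 0.5 * max(x[stim] - b))
    }
  }
})

test_that("anomaly III is low-SNR while category I is high-SNR by construction", {
  p <- default_protocol()  # the detection-corpus sampling rate
  t <- time_axis(p)
  base <- t < p$onset
  stim <- t >= p$onset & t < p$offset
  k <- max(1L, round(5 * p$rate))
  est_snr <- function(rec) {
    sapply(seq_len(nrow(rec$traces)), function(i) {
      x <- rec$traces[i, ]
      ev <- x[stim] - mean(x[base])
      sm <- stats::filter(ev, rep(1 / k, k), sides = 2)
      max(abs(sm), na.rm = TRUE) / sd(x[base])
    })
  }
  for (seed in 1:50) {
    bad <- generate_recording("anomaly_III", p, seed = seed)
    good <- generate_recording("category_I", p, seed = seed + 1000)
    expect_lt(max(est_snr(bad)), 2)
    expect_gt(max(est_snr(good)), 10)
  }
})

test_that("anomaly IV tails carry depolarizing bursts well above noise", {
  p <- default_protocol(1)
  t <- time_axis(p)
  tail_r <- t >= (p$offset + 5)
  for (seed in 1:20) {
    rec <- generate_recording("anomaly_IV", p, seed = seed)
    burst <- sapply(seq_len(nrow(rec$traces)), function(i) {
      x <- rec$traces[i, tail_r]
      b0 <- mean(rec$traces[i, t < p$onset])
      noise <- sd(rec$traces[i, t < p$onset])
      max(x - b0) / noise
    })
    expect_gt(max(burst), 5)
  }
})

test_that("dataset generation honours counts, determinism and the corpus presets", {
  counts <- c(category_I = 2L, anomaly_II = 3L)
  set <- generate_dataset(counts, default_protocol(1), seed = 3)
  expect_equal(as.integer(table(set_labels(set))[c("category_I", "anomaly_II")]),
               c(2L, 3L))
  set2 <- generate_dataset(counts, default_protocol(1), seed = 3)
  expect_identical(lapply(set$recordings, `[[`, "traces"),
                   lapply(set2$recordings, `[[`, "traces"))
  expect_equal(length(generate_dataset(c(category_I = 0L))), 0L)
  expect_error(generate_dataset(c(category_I = -1L)), "counts")
  corp <- anomaly_corpus_seed1()
  expect_equal(length(corp$train), 240L)
  expect_equal(length(corp$test), 144L)
  expect_equal(sum(binary_labels(corp$test) == "abnormal"), 72L)
  cc <- classifier_corpus(seed = 5)
  expect_equal(length(cc$train), 139L)
  expect_equal(length(cc$test), 124L)
})

test_that("the anomaly corpus round-trips through the native container", {
  corp <- anomaly_corpus_seed1()
  sub <- recording_set(corp$train$recordings[seq(1, 240, by = 24)])
  path <- tempfile(fileext = ".h5")
  write_container(sub, path)
  back <- read_container(path)
  expect_identical(lapply(back$recordings, `[[`, "traces"),
                   lapply(sub$recordings, `[[`, "traces"))
  expect_identical(set_labels(back), set_labels(sub))
  unlink(path)
})
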