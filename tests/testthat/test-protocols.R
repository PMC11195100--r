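test_that("calcium I-V protocol enumerates 12 steps from -80 to +30", {
  p <- ca_iv_protocol()
  steps <- p[p$label == "step", ]
  expect_equal(steps$value, seq(-80, 30, by = 10))
  expect_equal(nrow(steps), 12)
  expect_true(all(steps$duration == 150))
  holds <- p[p$label == "hold", ]
  expect_true(all(holds$value == -80))            # return to hold each sweep
  expect_equal(nrow(holds), 12)
})

test_that("potassium I-V protocol: 11 steps, 500 ms, 0.2-Hz pacing", {
  p <- k_iv_protocol()
  steps <- p[p$label == "step", ]
  expect_equal(steps$value, seq(-60, 40, by = 10))
  expect_true(all(steps$duration == 500))
  expect_true(all(p$value[p$label == "hold"] == -70))
  expect_true(all(p$duration[p$label == "hold"] == 5000))  # 0.2 Hz
})

test_that("M-current protocol: descending -30..-75 steps after a -20 prepulse", {
  p <- m_current_protocol()
  steps <- p[p$label == "step", ]
  expect_equal(steps$value, seq(-30, -75, by = -5))
  expect_equal(nrow(steps), 10)
  pre <- p[p$label == "prepulse", ]
  expect_true(all(pre$value == -20))
  expect_true(all(pre$duration == 300))
  # per-sweep active time is prepulse + step = 800 ms
  per_sweep <- tapply(p$duration[p$label != "hold"],
                      p$sweep[p$label != "hold"], sum)
  expect_true(all(per_sweep == 800))
})

test_that("ramp protocol covers rate x time and degenerates cleanly", {
  p <- ramp_protocol(50, 100)
  ramp <- p[p$label == "ramp", ]
  expect_equal(ramp$duration, 2000)           # 100 pA at 50 pA/s
  expect_equal(ramp$rate, 0.05)               # pA/ms
  p0 <- ramp_protocol(0, 100)
  expect_true(all(p0$value == 0) && all(p0$rate == 0))
})

test_that("NKB synchronization train delivers 200 pulses at 20 Hz", {
  p <- nkb_synchronization_protocol()
  train <- p[p$label == "train", ]
  expect_equal(train$duration / train$nkb_period, 200)
  expect_equal(train$nkb_period, 50)
  expect_gte(sum(p$duration[p$label == "post"]), 60000)
})

test_that("protocol constructors are pure (hash-stable)", {
  expect_identical(protocol_hash(k_iv_protocol()),
                   protocol_hash(k_iv_protocol()))
  expect_false(identical(protocol_hash(k_iv_protocol()),
                         protocol_hash(ca_iv_protocol())))
})

test_that("apply_drug sets the documented blocks and never mutates input", {
  p <- kndy_params("ovx")
  p2 <- apply_drug(p, "apamin")
  expect_equal(p2$channels$SK$block, 1)
  expect_equal(p$channels$SK$block, 0)          # input untouched
  expect_identical(apply_drug(p2, "apamin"), p2) # idempotent full block
  expect_identical(apply_drug(p, "none"), p)

  expect_equal(apply_drug(p, "iberiotoxin")$channels$BK$block, 1)
  expect_equal(apply_drug(p, "xe991")$channels$M$block, 1)
  expect_equal(apply_drug(p, "ttap2")$channels$T$block, 1)
  cd <- apply_drug(p, "cd")
  expect_equal(cd$channels$T$block, 1)
  expect_equal(cd$channels$Ca$block, 1)
  ttx <- apply_drug(p, "ttx")
  expect_equal(ttx$channels$NaT$block, 1)
  expect_equal(ttx$channels$NaP$block, 1)

  # HVA-subtype fractions are the per-state percentage contributions
  expect_equal(apply_drug(p, "nifedipine")$channels$Ca$block, 0.261)
  expect_equal(apply_drug(p, "conogvia")$channels$Ca$block, 0.251)
  expect_equal(apply_drug(p, "agaiva")$channels$Ca$block, 0.039)
  expect_equal(apply_drug(p, "snx")$channels$Ca$block, 0.311)
  e2 <- kndy_params("ovx_e2")
  expect_equal(apply_drug(e2, "nifedipine")$channels$Ca$block, 0.249)
  expect_equal(apply_drug(e2, "agaiva")$channels$Ca$block, 0.110)

  expect_error(apply_drug(p, "curare"), "unknown drug")
})

test_that("presets differ only in the estradiol-sensitive conductances", {
  a <- kndy_params("ovx")
  b <- kndy_params("ovx_e2")
  g <- function(p) vapply(p$channels, function(ch) ch$gbar, numeric(1))
  differs <- names(which(g(a) != g(b)))
  expect_setequal(differs, c("Ca", "T", "h", "TRPC5", "GIRK", "BK", "M"))
  for (nm in names(a$channels)) {
    expect_identical(a$channels[[nm]]$kin, b$channels[[nm]]$kin)
  }
})

test_that("shipped preset files reproduce the in-code presets", {
  for (st in c("ovx", "ovx_e2")) {
    f <- system.file("presets", paste0(st, ".yaml"), package = "kndysim")
    expect_true(nzchar(f))
    expect_equal(read_neuron_params(f), kndy_params(st))
  }
})
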