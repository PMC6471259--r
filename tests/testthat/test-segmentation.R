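test_that("centroid matches a naive per-axis mean", {
  expect_equal(compute_centroid(matrix(0, 25, 3)), c(0, 0, 0),
               ignore_attr = TRUE)
  const <- matrix(rep(c(1, 2, 3), each = 25), 25, 3)
  expect_equal(compute_centroid(const), c(1, 2, 3), ignore_attr = TRUE)
  for (s in 1:20) {
    fr <- random_frame(seed = s)
    naive <- vapply(1:3, function(a) {
      acc <- 0
      for (i in 1:25) acc <- acc + fr[i, a]
      acc / 25
    }, numeric(1))
    expect_equal(unname(compute_centroid(fr)), naive, tolerance = 1e-9)
  }
})

test_that("centroid difference series is the distance between consecutive centroids", {
  fr <- random_frame(seed = 1)
  static <- frames_to_sequence(list(fr, fr, fr, fr))
  expect_equal(centroid_difference_series(static)$values, rep(0, 3))

  # centroid stepping (+0.3, 0, +0.4) per frame: every distance is 0.5
  frames <- lapply(0:4, function(k) fr + rep(c(0.3, 0, 0.4) * k, each = 25))
  s <- centroid_difference_series(frames_to_sequence(frames))
  expect_equal(s$values, rep(0.5, 4), tolerance = 1e-9)
  expect_length(s$t, 4)

  frames <- lapply(1:6, function(k) random_frame(seed = 100 + k))
  seq6 <- frames_to_sequence(frames)
  s <- centroid_difference_series(seq6)
  naive <- vapply(2:6, function(t) {
    sqrt(sum((compute_centroid(frames[[t]]) -
                compute_centroid(frames[[t - 1]]))^2))
  }, numeric(1))
  expect_equal(s$values, naive, tolerance = 1e-9)
})

test_that("IMU difference series matches naive recomputation per channel", {
  n <- 40
  st <- random_imu_stream(n, seed = 2)
  for (ch in c("gyro", "accel")) {
    s <- imu_difference_series(st, ch)
    x <- st[[ch]]
    naive <- vapply(2:n, function(t) sqrt(sum((x[t, ] - x[t - 1, ])^2)),
                    numeric(1))
    expect_equal(s$values, naive, tolerance = 1e-9)
    expect_length(s$values, n - 1)
  }
  const <- imu_stream(1:5, matrix(2, 5, 3), matrix(-1, 5, 3), site = "AL")
  expect_equal(imu_difference_series(const, "gyro")$values, rep(0, 4))
  alt <- imu_stream(1:6, cbind(c(0, 1, 0, 1, 0, 1), 0, 0),
                    matrix(0, 6, 3), site = "AR")
  expect_equal(imu_difference_series(alt, "gyro")$values, rep(1, 5))
})

test_that("detect_span applies the strict relative threshold rule", {
  zero <- difference_series(1:5, rep(0, 5), "depth")
  expect_null(detect_span(zero))

  s <- difference_series(1:7, c(0, 0, 1.0, 0.8, 0.02, 0, 0), "depth")
  sp <- detect_span(s)  # 0.02 <= 0.05 * 1.0 so it is excluded
  expect_equal(sp$t_start, 3)
  expect_equal(sp$t_end, 4)

  one <- difference_series(1:5, c(0, 0, 0.7, 0, 0), "gyro@EL")
  sp1 <- detect_span(one)
  expect_equal(sp1$t_start, sp1$t_end)
  expect_equal(sp1$t_start, 3)

  # value exactly at the threshold is excluded (strictly greater than)
  tie <- difference_series(1:4, c(0.05, 1, 1, 0.05), "depth")
  spt <- detect_span(tie)
  expect_equal(c(spt$t_start, spt$t_end), c(2, 3))
})

test_that("difference series and spans obey offset/scale invariances", {
  for (s in 1:10) {
    st <- random_imu_stream(30, seed = s)
    shifted <- imu_stream(st$time, st$gyro + 3.7, st$accel - 1.2,
                          site = st$site)
    expect_equal(imu_difference_series(st, "gyro")$values,
                 imu_difference_series(shifted, "gyro")$values,
                 tolerance = 1e-9)
    expect_equal(imu_difference_series(st, "accel")$values,
                 imu_difference_series(shifted, "accel")$values,
                 tolerance = 1e-9)
    d <- imu_difference_series(st, "gyro")
    sp <- detect_span(d)
    for (c_scale in c(0.01, 3, 1000)) {
      scaled <- difference_series(d$t, d$values * c_scale, d$source)
      sps <- detect_span(scaled)
      expect_equal(sps$t_start, sp$t_start)
      expect_equal(sps$t_end, sp$t_end)
    }
  }
})

test_that("fuse_spans takes the earliest start and latest end", {
  mk <- function(a, b, src = "depth")
    structure(list(t_start = a, t_end = b, source = src), class = "span")
  single <- fuse_spans(list(mk(2, 5)))
  expect_equal(c(single$t_start, single$t_end), c(2, 5))
  f <- fuse_spans(list(mk(2, 5), mk(3, 9), mk(1, 4)))
  expect_equal(c(f$t_start, f$t_end), c(1, 9))
  expect_length(f$contributing, 3)

  set.seed(4)
  for (rep in 1:10) {
    spans <- lapply(1:9, function(i) {
      a <- runif(1, 0, 5)
      mk(a, a + runif(1, 0, 5))
    })
    fz <- fuse_spans(spans)
    starts <- vapply(spans, `[[`, numeric(1), "t_start")
    ends <- vapply(spans, `[[`, numeric(1), "t_end")
    expect_equal(fz$t_start, min(starts))
    expect_equal(fz$t_end, max(ends))
    # every contributing span is contained in the fused segment
    expect_true(all(starts >= fz$t_start & ends <= fz$t_end))
  }
  expect_error(fuse_spans(list(NULL, NULL)), "no activity")
})

test_that("segment_trial fuses all nine sources and handles static trials", {
  tr <- generate_trial("NW", 1.6, generator_config(), seed = 5)
  seg <- segment_trial(tr)
  expect_length(seg$contributing, 9)
  srcs <- vapply(seg$contributing, `[[`, character(1), "source")
  expect_setequal(srcs, c("depth", paste0("gyro@", sensor_sites()),
                          paste0("accel@", sensor_sites())))

  # static skeleton + moving IMUs: fused segment equals the IMU span union
  set.seed(8)
  fr <- random_frame(seed = 8)
  skel <- frames_to_sequence(rep(list(fr), 20))
  n <- 60
  imu <- lapply(sensor_sites(), function(s) {
    g <- matrix(0, n, 3)
    g[20:40, 1] <- sin(seq(0, 4 * pi, length.out = 21))
    imu_stream(seq_len(n) / 100, g, g, site = s)
  })
  names(imu) <- sensor_sites()
  tr2 <- trial("mixed", "u", skel, imu)
  seg2 <- segment_trial(tr2)
  expect_length(seg2$contributing, 8)  # depth span absent (all static)

  imu0 <- lapply(sensor_sites(), function(s)
    imu_stream(seq_len(10) / 100, matrix(0, 10, 3), matrix(0, 10, 3),
               site = s))
  names(imu0) <- sensor_sites()
  tr3 <- trial("static", "u", skel, imu0)
  expect_error(segment_trial(tr3), "no activity")
})

test_that("resample_uniform interpolates linearly with exact endpoints", {
  const <- resample_uniform(c(0, 1, 2), cbind(c(5, 5, 5)), 7)
  expect_equal(const$values[, 1], rep(5, 7))

  ramp <- resample_uniform(c(0, 1), cbind(c(0, 10)), 5)
  expect_equal(ramp$values[, 1], c(0, 2.5, 5, 7.5, 10))

  set.seed(9)
  v <- matrix(rnorm(24), 12, 2)
  ident <- resample_uniform(seq_len(12), v, 12)
  expect_equal(ident$values, v, tolerance = 1e-12)

  expect_error(resample_uniform(c(0, 1), cbind(c(0, 1)), 1), "at least 2")
})
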