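test_that("small-label removal uses the strictly-smaller rule", {
  v <- make_vol(c(12, 12, 12))
  v$lattice[2:5, 2:6, 2:6] <- 1L          # 100 voxels
  v$lattice[8, 8, 2:5] <- 2L              # 4 voxels
  v$lattice[10, 10, 2:6] <- 3L            # exactly 5 voxels
  out <- remove_small_labels(v, 5)
  expect_identical(label_ids(out), c(1L, 3L))
  expect_identical(attr(out, "removed"), 2L)
  expect_identical(out$lattice[2:5, 2:6, 2:6], v$lattice[2:5, 2:6, 2:6])
  # idempotent; empty input allowed
  expect_identical(remove_small_labels(out, 5)$lattice, out$lattice)
  expect_identical(remove_small_labels(make_vol(c(2, 2, 2)))$lattice,
                   make_vol(c(2, 2, 2))$lattice)
})

test_that("closing fills interior holes, opening shaves spikes, solids are fixed points", {
  v <- make_vol(c(12, 12, 12))
  v$lattice[3:8, 3:8, 3:8] <- 1L
  out <- close_open_labels(v)
  expect_identical(out$lattice, v$lattice)   # solid cube unchanged

  hole <- v
  hole$lattice[5, 5, 5] <- 0L
  out <- close_open_labels(hole)
  expect_equal(sum(out$lattice == 1L), sum(hole$lattice == 1L) + 1)
  expect_identical(out$lattice, v$lattice)
  expect_identical(attr(out, "changed"), 1L)

  spike <- v
  spike$lattice[9, 5, 5] <- 1L               # single-voxel spike on a face
  out <- close_open_labels(spike)
  expect_identical(out$lattice, v$lattice)
})

test_that("closing/opening never mixes labels and favors the original owner", {
  v <- make_vol(c(14, 10, 10))
  v$lattice[2:6, 2:8, 2:8] <- 1L
  v$lattice[7:12, 2:8, 2:8] <- 2L
  out <- close_open_labels(v)
  expect_identical(out$lattice, v$lattice)
})

test_that("thin labels merge with adjacent thin labels under the lowest ID", {
  v <- make_vol(c(10, 10, 12))
  v$lattice[2:8, 2:8, 2:9] <- 9L        # big 8-plane label
  v$lattice[3:5, 3:5, 10:11] <- 4L      # thin: 2 planes
  v$lattice[3:5, 3:5, 12] <- 6L         # thin: 1 plane, face-adjacent to 4
  out <- resolve_thin_labels(v, 2)
  # merged chain spans 3 planes -> survives as one label under ID 4
  expect_identical(label_ids(out), c(4L, 9L))
  expect_equal(sum(out$lattice == 4L), 9 * 2 + 9)
  expect_identical(attr(out, "merged")[["4"]], 6L)
  expect_identical(which(out$lattice == 9L), which(v$lattice == 9L))
})

test_that("a thin label whose neighbors are all non-thin is deleted", {
  v <- make_vol(c(10, 10, 14))
  v$lattice[2:8, 2:8, 2:11] <- 1L       # 10-plane label
  v$lattice[3:5, 3:5, 12:13] <- 2L      # thin, only neighbor is label 1
  out <- resolve_thin_labels(v, 2)
  expect_identical(label_ids(out), 1L)
  expect_identical(attr(out, "removed"), 2L)
  # orphan thin label (no neighbors at all) is deleted too
  v2 <- make_vol(c(8, 8, 8))
  v2$lattice[2:4, 2:4, 3] <- 5L
  expect_length(label_ids(resolve_thin_labels(v2, 2)), 0)
})

test_that("resolve_thin_labels leaves thick-only volumes alone and is idempotent", {
  v <- generate_spheroid(spheroid_spec(n_cells = 12, radius = 8, seed = 2))
  out <- resolve_thin_labels(v, 2)
  expect_identical(out$lattice, v$lattice)
  # idempotency on a volume that actually changes
  v$lattice[2, 2, 2] <- 50L
  once <- resolve_thin_labels(v, 2)
  twice <- resolve_thin_labels(once, 2)
  expect_identical(twice$lattice, once$lattice)
})

test_that("isotropic upsampling reproduces integer-ratio duplication and preserves labels", {
  v <- make_vol(c(6, 6, 10), spacing = c(1, 1, 2))
  v$lattice[2:4, 2:4, ] <- rep(1:10, each = 9)   # slice z carries value z
  up <- upsample_isotropic(v)
  expect_identical(dim(up), c(6L, 6L, 20L))
  expect_equal(up$spacing, c(1, 1, 1))
  # each original slice duplicated exactly twice, in order
  expect_identical(as.integer(up$lattice[3, 3, ]), rep(1:10, each = 2))
  expect_identical(label_ids(up), label_ids(v))
  # already-isotropic volume unchanged
  iso <- make_vol(c(4, 4, 4))
  expect_identical(upsample_isotropic(iso)$lattice, iso$lattice)
})

test_that("upsampled slice count follows the rounding formula for arbitrary spacings", {
  set.seed(42)
  for (i in 1:20) {
    nz <- sample(3:30, 1)
    dx <- runif(1, 0.2, 1)
    dz <- dx * runif(1, 1, 5)
    v <- make_vol(c(3, 3, nz), spacing = c(dx, dx, dz))
    v$lattice[2, 2, ] <- seq_len(nz)
    up <- upsample_isotropic(v)
    expect_identical(dim(up)[3], as.integer(floor(nz * dz / dx + 0.5)))
    # nearest-neighbor property: every output slice copies some input slice
    expect_true(all(up$lattice[2, 2, ] %in% seq_len(nz)))
    # monotone non-decreasing source index, no input slice skipped
    expect_identical(sort(unique(as.integer(up$lattice[2, 2, ]))), seq_len(nz))
  }
})

test_that("upsampling validates spacing preconditions", {
  expect_error(upsample_isotropic(make_vol(c(3, 3, 3), spacing = c(1, 2, 3))),
               "dx must equal dy")
  expect_error(upsample_isotropic(make_vol(c(3, 3, 3), spacing = c(2, 2, 1))),
               "dz must be >=")
})

test_that("pipeline removes exactly the injected debris and slivers and logs it", {
  # a world whose genuine cells all span >= 3 z-planes, so the thin-label
  # and small-object filters fire only on the injected artifacts
  v <- generate_spheroid(spheroid_spec(n_cells = 25, radius = 12, seed = 6))
  inj <- inject_artifacts(v, artifact_spec(n_debris = 3, n_slivers = 2),
                          seed = 21)
  man <- attr(inj, "manifest")
  res <- preprocess_pipeline(inj, upsample = FALSE)
  expect_setequal(res$log$removed, c(man$debris, man$slivers))
  expect_setequal(label_ids(res$volume), label_ids(v))
  # clean isotropic volume passes through up to close/open idempotence
  res2 <- preprocess_pipeline(v, upsample = FALSE)
  expect_length(res2$log$removed, 0)
  expect_identical(label_ids(res2$volume), label_ids(v))
  # stage log covers every label whose voxels changed
  diff_ids <- unique(c(inj$lattice[inj$lattice != res$volume$lattice],
                       res$volume$lattice[inj$lattice != res$volume$lattice]))
  diff_ids <- diff_ids[diff_ids > 0]
  expect_true(all(diff_ids %in% c(res$log$removed, res$log$morph_changed,
                                  unlist(res$log$thin_merged),
                                  as.integer(names(res$log$thin_merged)))))
})

test_that("remove/resolve stages never increase foreground and never invent IDs", {
  v <- generate_spheroid(spheroid_spec(n_cells = 18, radius = 9, seed = 9))
  inj <- inject_artifacts(v, artifact_spec(n_debris = 2, n_slivers = 1),
                          seed = 3)
  s1 <- remove_small_labels(inj, 5)
  expect_lte(sum(s1$lattice > 0), sum(inj$lattice > 0))
  s3 <- resolve_thin_labels(s1, 2)
  expect_lte(sum(s3$lattice > 0), sum(s1$lattice > 0))
  expect_true(all(label_ids(s3) %in% label_ids(inj)))
})
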