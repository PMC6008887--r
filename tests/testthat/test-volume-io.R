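make_ramp_volume <- function(d = c(4, 5, 6), spacing = c(0.115, 0.115, 0.115),
                             origin = c(0, 0, 0)) {
  image_volume(array(seq_len(prod(d)) / 7, d), spacing = spacing, origin = origin)
}

expect_volume_equal <- function(a, b, tol = 0, geom_tol = 1e-12) {
  expect_equal(dim(a$data), dim(b$data))
  expect_lt(max(abs(a$data - b$data)), tol + 1e-12)
  expect_equal(a$spacing, b$spacing, tolerance = geom_tol)
  expect_equal(a$origin, b$origin, tolerance = geom_tol)
}

test_that("world-coordinate mapping follows the voxel-center convention", {
  v <- image_volume(array(0, c(1, 1, 1)), spacing = rep(0.115, 3),
                    origin = c(1, 2, 3))
  expect_equal(as.vector(voxel_to_world(v, c(0, 0, 0))), c(1, 2, 3))
  w <- voxel_to_world(v, c(2, 3, 4))
  expect_equal(as.vector(w), c(1, 2, 3) + c(2, 3, 4) * 0.115)
  expect_equal(as.vector(world_to_voxel(v, w)), c(2, 3, 4), tolerance = 1e-12)
  expect_error(image_volume(array(0, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
})

test_that("NRRD round-trips across encodings, MetaImage and NIfTI round-trip", {
  v <- make_ramp_volume(spacing = c(0.1, 0.2, 0.3), origin = c(-1, 0.5, 2))
  for (enc in c("raw", "ascii", "gzip")) {
    p <- tempfile(fileext = ".nrrd")
    write_volume(v, p, encoding = enc)
    expect_volume_equal(read_volume(p), v)
    unlink(p)
  }
  for (ext in c(".mha", ".mhd", ".nii", ".nii.gz")) {
    p <- tempfile(fileext = ext)
    write_volume(v, p)
    # NIfTI headers store pixdim as float32
    gt <- if (grepl("nii", ext)) 1e-6 else 1e-12
    expect_volume_equal(read_volume(p), v, tol = 1e-9, geom_tol = gt)
    unlink(p)
  }
  expect_error(read_volume(tempfile(fileext = ".xyz")), "not found")
  p <- tempfile(fileext = ".xyz"); writeLines("x", p)
  expect_error(read_volume(p), "unsupported")
  expect_error(write_volume(v, tempfile(fileext = ".foo")), "unsupported")
})

test_that("corrupt NRRD headers are rejected", {
  p <- tempfile(fileext = ".nrrd")
  writeLines(c("not a nrrd", "type: double"), p)
  expect_error(read_volume(p), "magic")
})

test_that("NRRD and MetaImage agree with an independent writer and reader", {
  py <- Sys.which("python")
  expect_true(nzchar(py)) # same image ships python + SimpleITK
  d <- c(4, 4, 4)
  vals <- seq(0, by = 0.5, length.out = prod(d))
  for (ext in c(".nrrd", ".mha")) {
    p <- tempfile(fileext = ext)
    script <- sprintf(paste0(
      "import SimpleITK as sitk, numpy as np\n",
      "a = np.arange(%d, dtype=np.float64).reshape(%d, %d, %d) * 0.5\n",
      "img = sitk.GetImageFromArray(a)\n", # numpy axis order is z,y,x
      "img.SetSpacing((0.115, 0.115, 0.115))\n",
      "img.SetOrigin((1.0, 2.0, 3.0))\n",
      "sitk.WriteImage(img, %s, False)\n"),
      prod(d), d[3], d[2], d[1], deparse(p))
    sf <- tempfile(fileext = ".py"); writeLines(script, sf)
    expect_equal(system2(py, sf, stdout = FALSE, stderr = FALSE), 0L)
    v <- read_volume(p)
    expect_equal(as.vector(v$data), vals) # x fastest in both conventions
    expect_equal(v$spacing, rep(0.115, 3))
    expect_equal(v$origin, c(1, 2, 3))
    # and the reverse direction: our writer, their reader
    p2 <- tempfile(fileext = ext)
    write_volume(v, p2)
    chk <- sprintf(paste0(
      "import SimpleITK as sitk, numpy as np, sys\n",
      "img = sitk.ReadImage(%s)\n",
      "a = sitk.GetArrayFromImage(img)\n",
      "ok = (a.ravel()[:4] == [0, 0.5, 1.0, 1.5]).all() and ",
      "abs(np.array(img.GetSpacing()) - 0.115).max() < 1e-12 and ",
      "abs(np.array(img.GetOrigin()) - [1,2,3]).max() < 1e-12\n",
      "sys.exit(0 if ok else 1)\n"), deparse(p2))
    cf <- tempfile(fileext = ".py"); writeLines(chk, cf)
    expect_equal(system2(py, cf, stdout = FALSE, stderr = FALSE), 0L)
    unlink(c(p, p2, sf, cf))
  }
})

unit_cube_mesh <- function() {
  v <- unname(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),
    c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),
    c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6))
  surface_mesh(v, f, label = "cube")
}

test_that("PLY and STL mesh round-trips preserve geometry and connectivity", {
  m <- unit_cube_mesh()
  expect_equal(nrow(m$vertices), 8L)
  expect_equal(nrow(m$faces), 12L)
  p <- tempfile(fileext = ".ply")
  write_mesh(m, p)
  r <- read_mesh(p)
  expect_equal(r$vertices, m$vertices)
  expect_equal(r$faces, m$faces)
  p2 <- tempfile(fileext = ".stl")
  write_mesh(m, p2)
  r2 <- read_mesh(p2)
  expect_equal(nrow(r2$faces), 12L)
  expect_equal(nrow(r2$vertices), 8L) # soup welded back to 8 shared vertices
  expect_equal(apply(r2$vertices, 2, range), apply(m$vertices, 2, range))
  expect_error(write_mesh(surface_mesh(matrix(0, 0, 3), matrix(0L, 0, 3)),
                          tempfile(fileext = ".ply")), "empty")
  unlink(c(p, p2))
})

test_that("zero-area triangles are dropped at construction", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  m <- surface_mesh(v, rbind(c(1, 2, 3), c(1, 1, 2), c(2, 2, 2)))
  expect_equal(nrow(m$faces), 1L)
  expect_error(surface_mesh(v, rbind(c(1, 2, 4))), "out of range")
})

test_that("PLY written by an independent tool reads back identically", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  p <- tempfile(fileext = ".ply")
  script <- sprintf(paste0(
    "import trimesh, numpy as np\n",
    "m = trimesh.creation.box(extents=(1.0, 2.0, 3.0))\n",
    "m.export(%s, encoding='ascii')\n"), deparse(p))
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  expect_equal(system2(py, sf, stdout = FALSE, stderr = FALSE), 0L)
  m <- read_mesh(p)
  expect_equal(apply(m$vertices, 2, function(x) diff(range(x))), c(1, 2, 3),
               tolerance = 1e-6)
  expect_gte(nrow(m$faces), 12L)
  unlink(c(p, sf))
})
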