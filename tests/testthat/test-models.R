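# Independent parameter-count oracle: layer-by-layer arithmetic from the
# published stage tables, written without reference to the builder.
oracle_param_count <- function(name, input_side, width_factor = 1,
                               in_channels = 1) {
  stages <- switch(name,
    "VGG13" = ,
    "VGG13-FirstPool4" = ,
    "Res+VGG13" = list(n = c(2, 2, 2, 2, 2), ch = c(64, 128, 256, 512, 512)),
    "VGG12" = ,
    "VGG12-FirstPool4" = list(n = c(2, 2, 2, 2, 1),
                              ch = c(64, 128, 256, 512, 512)))
  first_pool <- if (grepl("FirstPool4", name)) 4 else 2
  residual <- name == "Res+VGG13"
  ch <- pmax(1, round(stages$ch * width_factor))
  total <- 0
  cin <- in_channels
  side <- input_side
  for (i in seq_along(stages$n)) {
    cc <- cin
    for (j in seq_len(stages$n[i])) {
      total <- total + 3 * 3 * cc * ch[i] + ch[i]
      cc <- ch[i]
    }
    if (residual) total <- total + cin * ch[i] + ch[i]   # 1x1 projection
    side <- side / (if (i == 1) first_pool else 2)
    cin <- ch[i]
  }
  hidden <- max(4, round(256 * width_factor))
  flat <- side^2 * ch[length(ch)]
  total + flat * hidden + hidden + hidden * 1 + 1
}

test_that("exactly the five registry architectures resolve", {
  expect_setequal(names(arch_registry()),
                  c("VGG13", "VGG13-FirstPool4", "VGG12",
                    "VGG12-FirstPool4", "Res+VGG13"))
  expect_error(build_model("VGG16", 64), "VGG13")
})

test_that("parameter counts match the layer-by-layer arithmetic oracle", {
  for (nm in names(arch_registry())) {
    m <- build_model(nm, input_side = 64, seed = 0, width_factor = 1 / 8)
    expect_identical(m$parameter_count,
                     as.integer(oracle_param_count(nm, 64, 1 / 8)),
                     info = nm)
  }
  # full-width check on one architecture
  expect_identical(build_model("VGG13", 64, seed = 0)$parameter_count,
                   as.integer(oracle_param_count("VGG13", 64)))
})

test_that("removing a convolution makes VGG12 strictly smaller than VGG13", {
  p13 <- build_model("VGG13", 64, 0, width_factor = 1 / 8)$parameter_count
  p12 <- build_model("VGG12", 64, 0, width_factor = 1 / 8)$parameter_count
  expect_lt(p12, p13)
})

test_that("FirstPool4 variants shrink feature maps early and carry fewer parameters", {
  for (base in c("VGG13", "VGG12")) {
    fp4 <- paste0(base, "-FirstPool4")
    s_base <- architecture_spec(base, 128, width_factor = 1 / 8)
    s_fp4 <- architecture_spec(fp4, 128, width_factor = 1 / 8)
    expect_lt(s_fp4$map_sides[1], s_base$map_sides[1])
    expect_lt(s_fp4$flat_features, s_base$flat_features)
    expect_lt(build_model(fp4, 128, 0, width_factor = 1 / 8)$parameter_count,
              build_model(base, 128, 0, width_factor = 1 / 8)$parameter_count)
  }
})

test_that("initialization is reproducible from the seed alone", {
  a <- build_model("VGG12", 32, seed = 5, width_factor = 1 / 16)
  b <- build_model("VGG12", 32, seed = 5, width_factor = 1 / 16)
  expect_identical(a$stages, b$stages)
  expect_identical(a$head, b$head)
  c <- build_model("VGG12", 32, seed = 6, width_factor = 1 / 16)
  expect_false(identical(a$head$W1, c$head$W1))
})

test_that("forward outputs are probabilities, order-equivariant and duplicate-consistent", {
  m <- build_model("VGG13", 32, seed = 1, width_factor = 1 / 16)
  set.seed(2)
  x <- array(runif(32 * 32 * 1 * 5), c(32, 32, 1, 5))
  p <- forward(m, x)
  expect_length(p, 5)
  expect_true(all(p > 0 & p < 1))
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(forward(m, x[, , , perm, drop = FALSE]), p[perm],
               tolerance = 1e-12)
  xdup <- x
  xdup[, , , 2] <- xdup[, , , 1]
  pd <- forward(m, xdup)
  expect_identical(pd[1], pd[2])
  expect_error(forward(m, array(0, c(16, 16, 1, 2))), "16 x 16")
  expect_error(build_model("VGG13", 100), "divisible")
})

test_that("zero-initialized skip projections reduce Res+VGG13 to VGG13", {
  res <- build_model("Res+VGG13", 32, seed = 3, width_factor = 1 / 16)
  vgg <- build_model("VGG13", 32, seed = 4, width_factor = 1 / 16)
  for (i in seq_along(res$stages)) {
    res$stages[[i]]$skip$w[] <- 0
    res$stages[[i]]$skip$b[] <- 0
    vgg$stages[[i]]$convs <- res$stages[[i]]$convs
  }
  vgg$head <- res$head
  set.seed(5)
  x <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  expect_equal(forward(res, x), forward(vgg, x), tolerance = 1e-12)
})

test_that("backpropagated gradients match numerical differentiation", {
  m <- build_model("VGG12", 32, seed = 9, width_factor = 1 / 32)
  set.seed(10)
  x <- array(runif(32 * 32 * 3), c(32, 32, 1, 3))
  y <- c(1, 0, 1)
  loss_of <- function(model) {
    p <- as.numeric(colonyqc:::forward_full(model, x)$p)
    bce_loss(y, p)
  }
  fw <- colonyqc:::forward_full(m, x, keep_cache = TRUE)
  glogit <- matrix((as.numeric(fw$p) - y) / 3, nrow = 1)
  gr <- colonyqc:::collect_grads(m, colonyqc:::backward_full(m, fw, glogit))
  par <- colonyqc:::collect_params(m)
  eps <- 1e-6
  set.seed(11)
  for (pname in c("s1_c1_w", "s3_c2_w", "s5_c1_b", "head_W1", "head_b2")) {
    k <- sample(length(par[[pname]]), 1)
    for (sgn in c(1, -1)) {
      p2 <- par
      p2[[pname]][k] <- p2[[pname]][k] + sgn * eps
      assign(if (sgn > 0) "up" else "down",
             loss_of(colonyqc:::restore_params(m, p2)))
    }
    numeric_grad <- (up - down) / (2 * eps)
    expect_equal(gr[[pname]][k], numeric_grad, tolerance = 1e-4,
                 info = pname)
  }
})
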