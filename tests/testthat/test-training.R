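test_that("cross-entropy losses hit their closed forms", {
  y <- c(1, 0, 1, 1, 0)
  expect_equal(cercatag:::binary_cross_entropy(rep(0.5, 5), y), log(2))
  expect_lt(cercatag:::binary_cross_entropy(ifelse(y == 1, 1, 0), y), 1e-5)
  # uniform directional activations: categorical loss is log(4)
  A <- matrix(0, 5, 4)
  dirs <- c(45, 135, 225, 315, 45)
  expect_equal(cercatag:::categorical_cross_entropy(A, dirs), log(4))
  # breakdown sums to total; zero weights give zero L2
  p <- tag_init(tag_masks("I"))
  for (nm in c("W_ff", "W_lat", "glob_out", "w_jump")) p[[nm]][] <- 0
  out <- tag_forward(p, matrix(0, 5, 16))
  lb <- tag_loss(out, y, dirs, p, train_config(lambda = 0.3))
  expect_equal(lb$l2_term, 0)
  expect_equal(lb$total, lb$bce_jump + lb$cce_direction + lb$l2_term +
                 lb$l1_term)
})

test_that("RMSprop iterates match a hand-stepped oracle on a quadratic", {
  cfg <- train_config("rmsprop", lr = 0.1)
  theta <- 2; state <- cercatag:::new_opt_state(1L, cfg)
  theta_hand <- 2; v_hand <- 0
  for (i in 1:5) {
    g <- theta            # d(theta^2/2)/dtheta
    st <- cercatag:::optimizer_step(theta, g, state, cfg)
    theta <- st$theta; state <- st$state
    g_hand <- theta_hand
    v_hand <- 0.99 * v_hand + 0.01 * g_hand^2
    theta_hand <- theta_hand - 0.1 * g_hand / (sqrt(v_hand) + 1e-8)
    expect_equal(theta, theta_hand, tolerance = 1e-12)
  }
})

test_that("Adam iterates match a hand-stepped oracle", {
  cfg <- train_config("adam", lr = 0.05)
  theta <- -1.5; state <- cercatag:::new_opt_state(1L, cfg)
  th <- -1.5; m <- 0; v <- 0
  for (t in 1:5) {
    g <- th^3             # gradient of theta^4/4
    st <- cercatag:::optimizer_step(theta, theta^3, state, cfg)
    theta <- st$theta; state <- st$state
    m <- 0.9 * m + 0.1 * g
    v <- 0.999 * v + 0.001 * g^2
    mh <- m / (1 - 0.9^t); vh <- v / (1 - 0.999^t)
    th <- th - 0.05 * mh / (sqrt(vh) + 1e-8)
    expect_equal(theta, th, tolerance = 1e-12)
  }
})

test_that("analytic TAG gradients match central finite differences", {
  set.seed(42)
  X <- matrix(rnorm(10 * 16, 0, 0.5), 10, 16)
  y <- rbinom(10, 1, 0.5)
  dirs <- sample(c(45, 135, 225, 315), 10, TRUE)
  cfg <- train_config(lambda = 1e-4)
  for (variant in c("I", "I+L+G")) {
    mask <- tag_masks(variant)
    p <- perturbed_tag_params(variant)
    lossfun <- function(pp)
      tag_loss(tag_forward(pp, X, mask), y, dirs, pp, cfg)$total
    g <- cercatag:::tag_gradient(p, X, y, dirs, cfg, mask)
    theta <- flatten_tag(p); gflat <- unlist(g)
    skel <- unclass(p); h <- 1e-6
    num <- vapply(seq_along(theta), function(i) {
      tp <- theta; tp[i] <- tp[i] + h
      tm <- theta; tm[i] <- tm[i] - h
      (lossfun(rebuild_tag(tp, skel, mask)) -
         lossfun(rebuild_tag(tm, skel, mask))) / (2 * h)
    }, numeric(1))
    msk <- unlist(cercatag:::tag_mask_numeric(mask))
    rel <- abs(gflat - num * msk) / pmax(abs(num * msk), 1e-4)
    expect_lt(max(rel[msk == 1]), 1e-5)
    expect_true(all(gflat[msk == 0] == 0))
  }
})

test_that("analytic comparator gradients match central finite differences", {
  set.seed(43)
  X <- matrix(rnorm(10 * 16, 0, 0.5), 10, 16)
  y <- rbinom(10, 1, 0.5)
  cfg <- train_config("adam", lambda = 1e-4, l1 = 1e-3)
  m <- build_mlp(mlp_spec(3, 4), seed = 3)
  loss <- function(pp) mlp_loss(mlp_forward(pp, X), y, pp, cfg)$total
  g <- unlist(cercatag:::mlp_gradient(m, X, y, cfg))
  theta <- unlist(unclass(m)); skel <- unclass(m); h <- 1e-6
  num <- vapply(seq_along(theta), function(i) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    p1 <- cercatag:::unflatten_params(tp, skel); class(p1) <- "mlp_params"
    p2 <- cercatag:::unflatten_params(tm, skel); class(p2) <- "mlp_params"
    (loss(p1) - loss(p2)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g - num) / pmax(abs(num), 1e-4)), 1e-5)
})

test_that("training is seeded, masked and inert at zero learning rate", {
  ds <- tiny_dataset()
  cfg <- train_config("rmsprop", lr = 1e-2, epochs = 3, seed = 5)
  p0 <- tag_init(tag_masks("I+L"))
  t1 <- train_model(p0, ds, cfg)
  t2 <- train_model(p0, ds, cfg)
  expect_equal(t1, t2, tolerance = 1e-15)
  # masked-out weights stay exactly zero after training
  mask <- attr(t1, "mask")
  expect_true(all(t1$W_ff[!mask$ff] == 0))
  expect_true(all(t1$W_lat[!mask$lat] == 0))
  expect_true(all(t1$glob_out[!mask$glob_out] == 0))
  expect_true(all(t1$w_jump[!mask$jump] == 0))
  # and weights inside the mask moved
  expect_false(all(t1$W_ff[mask$ff] == p0$W_ff[mask$ff]))
  # zero learning rate leaves every parameter untouched
  frozen <- train_model(p0, ds, train_config("rmsprop", lr = 0, epochs = 2))
  expect_identical(frozen$W_ff, p0$W_ff)
  expect_identical(frozen$w_jump, p0$w_jump)
})

test_that("the training loss decreases over epochs on the standard task", {
  ds <- tiny_dataset()
  tr <- train_model(tag_init(tag_masks("I+L+G")), ds,
                    train_config("rmsprop", epochs = 10, seed = 1))
  trace <- attr(tr, "loss_trace")
  expect_identical(length(trace), 10L)
  expect_lt(trace[10], trace[1])
})

test_that("weight decay shrinks the trained weight norm", {
  ds <- tiny_dataset()
  base <- train_model(tag_init(tag_masks("I+L+G")), ds,
                      train_config("rmsprop", epochs = 10, lambda = 0,
                                   seed = 2))
  dec <- train_model(tag_init(tag_masks("I+L+G")), ds,
                     train_config("rmsprop", epochs = 10, lambda = 0.05,
                                  seed = 2))
  expect_lt(cercatag:::sum_sq_weights(dec), cercatag:::sum_sq_weights(base))
})

test_that("L1-sparsified comparator training concentrates weights near zero", {
  ds <- tiny_dataset()
  std <- train_model(build_mlp(mlp_spec(1, 8), seed = 4), ds,
                     train_config("adam", lr = 1e-3, epochs = 40, lambda = 0,
                                  seed = 4))
  l1 <- train_model(build_mlp(mlp_spec(1, 8), seed = 4), ds,
                    train_config("adam", lr = 1e-3, epochs = 40, lambda = 0,
                                 l1 = 1e-2, seed = 4))
  expect_lt(median(abs(unlist(l1$W))), median(abs(unlist(std$W))))
})
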