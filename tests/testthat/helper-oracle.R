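# Independent brute-force oracles, written as plain loops straight from the
# indicator definitions. Deliberately shares no code with the package.

oracle_smooth_vec <- function(x, w) {
  n <- length(x)
  h <- (w - 1) %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - h)
    hi <- min(n, i + h)
    s <- 0
    for (j in lo:hi) s <- s + x[j]
    out[i] <- s / (hi - lo + 1)
  }
  out
}

oracle_speeds <- function(t, x, y, z, w) {
  xs <- oracle_smooth_vec(x, w)
  ys <- oracle_smooth_vec(y, w)
  zs <- oracle_smooth_vec(z, w)
  n <- length(t)
  v <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    d <- sqrt((xs[i + 1] - xs[i])^2 + (ys[i + 1] - ys[i])^2 +
                (zs[i + 1] - zs[i])^2)
    v[i] <- d / (t[i + 1] - t[i])
  }
  v
}

# state-machine segmentation over raw frames
oracle_segment <- function(rec) {
  fr <- as.data.frame(rec$frames)
  n <- nrow(fr)
  atts <- list()
  idle_start <- if (fr$ball_state[1] == "idle") 1 else NA
  i <- 1
  while (i <= n) {
    st <- fr$ball_state[i]
    if (st == "idle" && (i == 1 || fr$ball_state[i - 1] != "idle")) {
      idle_start <- i
    }
    if (st == "flying" && (i == 1 || fr$ball_state[i - 1] != "flying")) {
      launch_i <- i
      j <- i
      while (j < n && fr$ball_state[j + 1] == "flying") j <- j + 1
      apex_i <- launch_i
      for (m in launch_i:j) {
        if (fr$ball_y[m] > fr$ball_y[apex_i]) apex_i <- m
      }
      if (j < n && fr$ball_state[j + 1] %in% c("caught", "missed")) {
        end_i <- j + 1
        outcome <- if (fr$ball_state[j + 1] == "caught") "success" else "fail"
      } else {
        end_i <- j
        outcome <- "fail"
      }
      spawn_t <- if (!is.na(idle_start) && idle_start < launch_i) {
        fr$t[idle_start]
      } else {
        fr$t[launch_i]
      }
      atts[[length(atts) + 1]] <- list(
        t_spawn = spawn_t, t_launch = fr$t[launch_i],
        t_apex = fr$t[apex_i], t_end = fr$t[end_i], outcome = outcome,
        hand = if (fr$ball_x[end_i] >= fr$ball_x[launch_i]) "right" else "left",
        target = c(fr$ball_x[end_i], fr$ball_y[end_i], fr$ball_z[end_i]))
      i <- j
    }
    i <- i + 1
  }
  for (k in seq_along(atts)) {
    atts[[k]]$window_end <- if (k < length(atts)) {
      atts[[k + 1]]$t_launch
    } else {
      fr$t[n]
    }
  }
  atts
}

oracle_in_band <- function(px, py, pz, target, cfg, mode) {
  if (mode == "h") {
    abs(px - target[1]) <= cfg$axis_band_m
  } else if (mode == "v") {
    abs(py - target[2]) <= cfg$axis_band_m
  } else {
    sqrt((px - target[1])^2 + (py - target[2])^2 +
           (pz - target[3])^2) <= cfg$catch_radius_m
  }
}

oracle_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else sum(x) / length(x)
}

# the full 25-indicator computation, loops only
oracle_indicators <- function(rec, cfg) {
  fr <- as.data.frame(rec$frames)
  side <- rec$settings$affected_side
  pre <- if (side == "left") "lh" else "rh"
  npre <- if (side == "left") "rh" else "lh"
  ax <- fr[[paste0(pre, "_x")]]
  ay <- fr[[paste0(pre, "_y")]]
  az <- fr[[paste0(pre, "_z")]]
  atts <- oracle_segment(rec)
  aff <- Filter(function(a) a$hand == side, atts)
  out <- as.list(setNames(rep(NA_real_, 25),
                          c(paste0("hmi_", 1:6), paste0("vmi_", 1:6),
                            paste0("fbmi_", 1:13))))
  if (length(aff) == 0) return(out)

  w <- cfg$smoothing_window_frames
  v_all <- oracle_speeds(fr$t, ax, ay, az, w)

  per <- list()
  for (a in aff) {
    win <- which(fr$t >= a$t_spawn & fr$t <= a$window_end)
    res <- list()
    for (mode in c("h", "v")) {
      inb <- oracle_in_band(ax[win], ay[win], az[win], a$target, cfg, mode)
      entries <- 0
      first_e <- NA_real_
      last_e <- NA_real_
      for (i in seq_along(inb)) {
        if (inb[i] && (i == 1 || !inb[i - 1])) {
          entries <- entries + 1
          if (is.na(first_e)) first_e <- fr$t[win[i]] - a$t_spawn
          last_e <- fr$t[win[i]] - a$t_spawn
        }
      }
      aim <- NA_real_
      for (i in seq_along(inb)) {
        if (inb[i] && fr$t[win[i]] >= a$t_apex) {
          aim <- fr$t[win[i]] - a$t_apex
          break
        }
      }
      # stabilization within [t_spawn, t_end]
      stab <- NA_real_
      if (a$outcome == "success") {
        cw <- which(fr$t >= a$t_spawn & fr$t <= a$t_end)
        if (length(cw) >= 2) {
          inb2 <- oracle_in_band(ax[cw], ay[cw], az[cw], a$target, cfg,
                                 mode)
          vv <- oracle_speeds(fr$t[cw], ax[cw], ay[cw], az[cw], w)
          ok <- inb2[-length(cw)] & vv < cfg$stabilization_speed_mps
          i <- 1
          while (i <= length(ok)) {
            if (ok[i]) {
              j <- i
              while (j < length(ok) && ok[j + 1]) j <- j + 1
              if (fr$t[cw[j + 1]] - fr$t[cw[i]] >=
                    cfg$stabilization_dwell_s) {
                stab <- a$t_end - fr$t[cw[i]]
                break
              }
              i <- j
            }
            i <- i + 1
          }
        }
      }
      res[[mode]] <- list(first = first_e, last = last_e, n = entries,
                          aim = aim, stab = stab)
    }
    res$catch <- if (a$outcome == "success") a$t_end - a$t_spawn else NA_real_
    res$l2c <- if (a$outcome == "success") a$t_end - a$t_launch else NA_real_
    per[[length(per) + 1]] <- res
  }

  gx <- function(f) sapply(per, f)
  out$hmi_1 <- oracle_mean(gx(function(p) p$h$first))
  out$hmi_2 <- oracle_mean(gx(function(p) p$h$last))
  out$hmi_3 <- oracle_mean(gx(function(p) p$catch))
  out$hmi_4 <- oracle_mean(gx(function(p) p$h$aim))
  out$hmi_5 <- oracle_mean(gx(function(p) p$h$stab))
  out$hmi_6 <- oracle_mean(gx(function(p) p$h$n))
  out$vmi_1 <- oracle_mean(gx(function(p) p$v$first))
  out$vmi_2 <- oracle_mean(gx(function(p) p$v$last))
  out$vmi_3 <- out$hmi_3
  out$vmi_4 <- oracle_mean(gx(function(p) p$v$aim))
  out$vmi_5 <- oracle_mean(gx(function(p) p$v$stab))
  out$vmi_6 <- oracle_mean(gx(function(p) p$v$n))

  out$fbmi_1 <- oracle_mean(gx(function(p) p$l2c))
  ct <- gx(function(p) p$catch)
  out$fbmi_2 <- if (all(is.na(ct))) NA_real_ else sum(ct[!is.na(ct)])

  plen <- function(x, y, z) {
    xs <- oracle_smooth_vec(x, w)
    ys <- oracle_smooth_vec(y, w)
    zs <- oracle_smooth_vec(z, w)
    s <- 0
    for (i in seq_len(length(x) - 1)) {
      s <- s + sqrt((xs[i + 1] - xs[i])^2 + (ys[i + 1] - ys[i])^2 +
                      (zs[i + 1] - zs[i])^2)
    }
    s
  }
  aff_len <- plen(ax, ay, az)
  nor_len <- plen(fr[[paste0(npre, "_x")]], fr[[paste0(npre, "_y")]],
                  fr[[paste0(npre, "_z")]])
  out$fbmi_3 <- aff_len
  out$fbmi_4 <- if (aff_len > 0) nor_len / aff_len else NA_real_

  pool <- function(lo_f, hi_f) {
    v <- c()
    for (a in atts) {
      lo <- lo_f(a)
      hi <- hi_f(a)
      for (i in seq_along(v_all)) {
        if (fr$t[i] >= lo && fr$t[i + 1] <= hi) v <- c(v, v_all[i])
      }
    }
    v
  }
  sstats <- function(v) {
    if (length(v) == 0) return(c(NA_real_, NA_real_, NA_real_))
    m <- sum(v) / length(v)
    c(max(v), m, sqrt(sum((v - m)^2) / length(v)))
  }
  s_pre <- sstats(pool(function(a) a$t_spawn, function(a) a$t_apex))
  s_post <- sstats(pool(function(a) a$t_apex, function(a) a$t_end))
  out$fbmi_5 <- s_pre[1]; out$fbmi_6 <- s_pre[2]; out$fbmi_7 <- s_pre[3]
  out$fbmi_8 <- s_post[1]; out$fbmi_9 <- s_post[2]; out$fbmi_10 <- s_post[3]

  out$fbmi_11 <- max(abs(ax - ax[1]))
  out$fbmi_12 <- max(abs(ay - ay[1]))
  out$fbmi_13 <- max(abs(az - az[1]))
  out
}

# O(n^2) silhouette straight from the definition
oracle_silhouette <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i] & seq_len(n) != i)
    if (length(own) == 0) {
      s[i] <- 0
      next
    }
    a <- mean(sapply(own, function(j) sqrt(sum((X[i, ] - X[j, ])^2))))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      oth <- which(labels == cl)
      d <- mean(sapply(oth, function(j) sqrt(sum((X[i, ] - X[j, ])^2))))
      if (d < b) b <- d
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

# exact two-sided signed-rank p by full 2^n enumeration
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ws <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    ws[m + 1] <- sum(r[signs == 1])
  }
  p_le <- mean(ws <= W + 1e-9)
  p_ge <- mean(ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Spearman by midranks computed from scratch, then the Pearson formula
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n)) {
      less <- sum(v < v[i])
      eq <- sum(v == v[i])
      r[i] <- less + (eq + 1) / 2
    }
    r
  }
  rx <- midrank(x)
  ry <- midrank(y)
  mx <- mean(rx)
  my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# Rand index between two labelings
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  tot <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      tot <- tot + 1
      if ((a[i] == a[j]) == (b[i] == b[j])) agree <- agree + 1
    }
  }
  agree / tot
}
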