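# Architecture templates and their hyperparameter search spaces. The spaces
# bound what random_search() may sample; fit_classifier() itself also
# accepts smaller configs so that smoke-scale models can be trained on a
# laptop CPU.

ARCHITECTURES <- c("cnn", "cnn_lstm_fc", "resnet1d", "convmixer1d",
                   "inception_time", "nearest_centroid")

# per-block filter and kernel choices of the CNN-style search space
CNN_BLOCK_FILTERS <- list(c(16, 32, 64), c(32, 64, 128), c(64, 128, 256),
                          c(128, 256, 512), c(256, 512, 1024), c(256, 512))
CNN_BLOCK_KERNELS <- list(c(3, 5, 7), c(3, 5), c(3, 5), 3, 3, 3)

config_space <- function(architecture) {
  switch(architecture,
    cnn = list(
      n_blocks = 5:6, block_filters = CNN_BLOCK_FILTERS,
      block_kernels = CNN_BLOCK_KERNELS,
      fc1 = c(512, 1024), fc2 = c(256, 512, 700),
      dropout1 = c(0.1, 0.6), dropout2 = c(0.1, 0.6),
      batch_size = c(16, 32, 64), lr = c(1e-5, 1e-3)),
    cnn_lstm_fc = list(
      n_blocks = 6, block_filters = CNN_BLOCK_FILTERS,
      block_kernels = CNN_BLOCK_KERNELS,
      lstm_hidden = c(64, 128, 192, 256, 320, 384, 448, 512),
      lstm_layers = 1:2, lstm_bidirectional = c(FALSE, TRUE),
      fc = c(128, 256, 512, 1024), dropout = c(0.1, 0.5),
      batch_size = c(16, 32, 64, 128), lr = c(1e-5, 1e-3)),
    resnet1d = list(
      filters = c(16, 32, 64), input_kernel = 7, depth = 2:6,
      batch_size = c(16, 32, 64), lr = c(1e-5, 1e-3)),
    convmixer1d = list(
      filters = c(16, 32, 64, 128), stem_kernel = 7, depth = 4:8,
      dw_kernel = c(3, 5, 7, 9), dropout = c(0, 0.4),
      batch_size = c(16, 32, 64, 128), lr = c(1e-5, 1e-3)),
    inception_time = list(
      n_blocks = 3:9, filters = c(16, 32, 64, 96),
      base_kernel = c(7, 9, 11), bottleneck = c(16, 32),
      dropout = c(0, 0.5), batch_size = c(32, 64, 128), lr = c(1e-5, 1e-3)),
    nearest_centroid = list(),
    stop("unknown architecture: ", architecture)
  )
}

pick <- function(set) if (length(set) == 1) set else sample(set, 1)

#' Sample a classifier configuration from an architecture's search space
#'
#' Draws one configuration uniformly from the bounded hyperparameter space
#' of the given template (discrete sets for structural choices, log-uniform
#' for the learning rate, uniform for dropout rates).
#'
#' @param architecture one of `"cnn"`, `"cnn_lstm_fc"`, `"resnet1d"`,
#'   `"convmixer1d"`, `"inception_time"`.
#' @return a named list usable as the `config` of [fit_classifier()].
#' @export
sample_config <- function(architecture) {
  sp <- config_space(architecture)
  lr <- exp(stats::runif(1, log(sp$lr[1]), log(sp$lr[2])))
  cfg <- switch(architecture,
    cnn = {
      nb <- pick(sp$n_blocks)
      list(n_blocks = nb,
           filters = vapply(seq_len(nb), function(i) pick(sp$block_filters[[i]]), numeric(1)),
           kernels = vapply(seq_len(nb), function(i) pick(sp$block_kernels[[i]]), numeric(1)),
           fc1 = pick(sp$fc1), fc2 = pick(sp$fc2),
           dropout1 = stats::runif(1, sp$dropout1[1], sp$dropout1[2]),
           dropout2 = stats::runif(1, sp$dropout2[1], sp$dropout2[2]),
           batch_size = pick(sp$batch_size))
    },
    cnn_lstm_fc = {
      nb <- sp$n_blocks
      list(n_blocks = nb,
           filters = vapply(seq_len(nb), function(i) pick(sp$block_filters[[i]]), numeric(1)),
           kernels = vapply(seq_len(nb), function(i) pick(sp$block_kernels[[i]]), numeric(1)),
           lstm_hidden = pick(sp$lstm_hidden), lstm_layers = pick(sp$lstm_layers),
           lstm_bidirectional = pick(sp$lstm_bidirectional),
           fc = pick(sp$fc),
           dropout = stats::runif(1, sp$dropout[1], sp$dropout[2]),
           batch_size = pick(sp$batch_size))
    },
    resnet1d = list(filters = pick(sp$filters), input_kernel = 7,
                    depth = pick(sp$depth), batch_size = pick(sp$batch_size)),
    convmixer1d = list(filters = pick(sp$filters), stem_kernel = 7,
                       depth = pick(sp$depth), dw_kernel = pick(sp$dw_kernel),
                       dropout = stats::runif(1, sp$dropout[1], sp$dropout[2]),
                       batch_size = pick(sp$batch_size)),
    inception_time = list(n_blocks = pick(sp$n_blocks),
                          filters = pick(sp$filters),
                          base_kernel = pick(sp$base_kernel),
                          bottleneck = pick(sp$bottleneck),
                          dropout = stats::runif(1, sp$dropout[1], sp$dropout[2]),
                          batch_size = pick(sp$batch_size)),
    stop("no sampleable space for ", architecture)
  )
  cfg$lr <- lr
  cfg
}

default_config <- function(architecture) {
  # small end of each search space: feasible on one CPU core
  switch(architecture,
    cnn = list(n_blocks = 2, filters = c(16, 32), kernels = c(7, 3),
               pool = 2, fc1 = 64, fc2 = 32, dropout1 = 0.1, dropout2 = 0.1,
               batch_size = 16, lr = 1e-3),
    cnn_lstm_fc = list(n_blocks = 2, filters = c(16, 32), kernels = c(7, 3),
                       pool = 4, lstm_hidden = 32, lstm_layers = 1,
                       lstm_bidirectional = FALSE, fc = 64, dropout = 0.1,
                       batch_size = 16, lr = 1e-3),
    resnet1d = list(filters = 16, input_kernel = 7, depth = 2,
                    batch_size = 16, lr = 1e-3),
    convmixer1d = list(filters = 16, stem_kernel = 7, depth = 4,
                       dw_kernel = 5, dropout = 0.1, batch_size = 16, lr = 1e-3),
    inception_time = list(n_blocks = 3, filters = 16, base_kernel = 9,
                          bottleneck = 16, dropout = 0.1, batch_size = 32,
                          lr = 1e-3),
    nearest_centroid = list(),
    stop("unknown architecture: ", architecture)
  )
}

build_network <- function(architecture, config, input_len, in_ch, n_classes) {
  cfg <- utils::modifyList(default_config(architecture), config)
  pool <- if (!is.null(cfg$pool)) cfg$pool else 2
  conv_stack <- function(filters, kernels, pool) {
    layers <- list()
    ch <- in_ch
    len <- input_len
    for (i in seq_along(filters)) {
      layers <- c(layers, list(nn_conv1d(ch, filters[i], kernels[i]), nn_relu()))
      if (len %/% pool >= 2) {
        layers <- c(layers, list(nn_maxpool(pool)))
        len <- len %/% pool
      }
      ch <- filters[i]
    }
    list(layers = layers, ch = ch, len = len)
  }
  net <- switch(architecture,
    cnn = {
      st <- conv_stack(cfg$filters, cfg$kernels, pool)
      do.call(nn_seq, c(st$layers, list(
        nn_gap(),
        nn_dense(st$ch, cfg$fc1), nn_relu(), nn_dropout(cfg$dropout1),
        nn_dense(cfg$fc1, cfg$fc2), nn_relu(), nn_dropout(cfg$dropout2),
        nn_dense(cfg$fc2, n_classes))))
    },
    cnn_lstm_fc = {
      st <- conv_stack(cfg$filters, cfg$kernels, pool)
      lstm_of <- function(in_ch, h) {
        if (isTRUE(cfg$lstm_bidirectional)) {
          list(layer = nn_parallel(nn_seq(nn_lstm(in_ch, h)),
                                   nn_seq(nn_rev(), nn_lstm(in_ch, h), nn_rev())),
               out = 2 * h)
        } else {
          list(layer = nn_lstm(in_ch, h), out = h)
        }
      }
      layers <- st$layers
      ch <- st$ch
      for (l in seq_len(cfg$lstm_layers)) {
        lw <- lstm_of(ch, cfg$lstm_hidden)
        layers <- c(layers, list(lw$layer))
        ch <- lw$out
      }
      do.call(nn_seq, c(layers, list(
        nn_gap(), nn_dense(ch, cfg$fc), nn_relu(), nn_dropout(cfg$dropout),
        nn_dense(cfg$fc, n_classes))))
    },
    resnet1d = {
      f <- cfg$filters
      blocks <- lapply(seq_len(cfg$depth), function(i) {
        nn_res(nn_seq(nn_conv1d(f, f, 3), nn_relu(), nn_conv1d(f, f, 3)))
      })
      do.call(nn_seq, c(list(nn_conv1d(in_ch, f, cfg$input_kernel), nn_relu(),
                             nn_maxpool(pool)),
                        blocks,
                        list(nn_gap(), nn_dense(f, n_classes))))
    },
    convmixer1d = {
      f <- cfg$filters
      blocks <- unlist(lapply(seq_len(cfg$depth), function(i) {
        list(nn_res(nn_seq(nn_dwconv1d(f, cfg$dw_kernel), nn_gelu()),
                    act = "none"),
             nn_conv1d(f, f, 1), nn_gelu(), nn_dropout(cfg$dropout))
      }), recursive = FALSE)
      do.call(nn_seq, c(list(nn_conv1d(in_ch, f, cfg$stem_kernel), nn_gelu(),
                             nn_maxpool(pool)),
                        blocks,
                        list(nn_gap(), nn_dense(f, n_classes))))
    },
    inception_time = {
      f <- cfg$filters
      bt <- cfg$bottleneck
      k <- cfg$base_kernel
      ch <- in_ch
      blocks <- list()
      for (i in seq_len(cfg$n_blocks)) {
        body <- nn_seq(
          nn_conv1d(ch, bt, 1), nn_relu(),
          nn_parallel(nn_seq(nn_conv1d(bt, f, k)),
                      nn_seq(nn_conv1d(bt, f, 2 * k - 1)),
                      nn_seq(nn_conv1d(bt, f, 4 * k - 3))))
        proj <- if (ch == 3 * f) NULL else nn_seq(nn_conv1d(ch, 3 * f, 1))
        blocks <- c(blocks, list(nn_res(body, proj = proj)))
        ch <- 3 * f
      }
      do.call(nn_seq, c(list(nn_maxpool(pool)), blocks,
                        list(nn_gap(), nn_dropout(cfg$dropout),
                             nn_dense(ch, n_classes))))
    },
    stop("no network template for ", architecture)
  )
  list(net = net, config = cfg)
}
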