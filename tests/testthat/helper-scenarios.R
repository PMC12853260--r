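# shared builders for synthetic scenarios and hand-made tensors

# bivariate VAR(1): x2 driven by x1 with the given coupling
bivariate_net <- function(coupling = 0.5, self = 0) {
  var_network(2, self = self,
              couplings = data.frame(source = 1, target = 2, value = coupling))
}

# 4-channel network with a few known couplings, used for oracle checks
four_channel_net <- function() {
  var_network(4, self = c(0.4, 0.3, 0.2, 0.35),
              couplings = data.frame(source = c(1, 2, 3), target = c(2, 3, 1),
                                     value = c(0.5, -0.4, 0.3)))
}

# wrap a raw difference array into a delta_gc object for summary tests
fake_delta <- function(delta, time = NULL, channels = NULL) {
  stopifnot(length(dim(delta)) == 3)
  channels <- channels %||% paste0("ch", seq_len(dim(delta)[1]))
  time <- time %||% ((seq_len(dim(delta)[3]) - 1) * 0.13)
  dimnames(delta) <- list(channels, channels, NULL)
  structure(list(delta = delta, time = time, channels = channels),
            class = "delta_gc")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# three channels in two ROIs: A = {ch1, ch2}, B = {ch3}
toy_map3 <- function() {
  channel_map(paste0("ch", 1:3), roi = c("A", "A", "B"),
              hemisphere = c("ipsilesional", "ipsilesional", "contralesional"))
}
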