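#' Abstract SIMT device model
#'
#' A purely arithmetic description of a wide SIMT accelerator, used by the
#' tile planner: number of streaming multiprocessors (SMs), maximum resident
#' threads per SM, hardware cap on simultaneously scheduled blocks per SM,
#' warp size, and optional register/shared-memory/user block limits. No
#' hardware is probed; the model only feeds the occupancy and tile-size
#' arithmetic.
#'
#' @param sm_num Number of streaming multiprocessors.
#' @param t_max Maximum resident threads per SM.
#' @param b_hw Hardware cap on blocks per SM.
#' @param warp_size Threads per warp (scheduling unit).
#' @param b_reg,b_shr,b_user Optional block limits from register pressure,
#'   shared memory, or user configuration; `Inf` means unconstrained.
#' @return A `device_model` list.
#' @export
#' @examples
#' device_model()  # the default 14-SM profile
device_model <- function(sm_num = 14L, t_max = 1024L, b_hw = 8L,
                         warp_size = 32L, b_reg = Inf, b_shr = Inf,
                         b_user = Inf) {
  for (v in list(sm_num, t_max, b_hw, warp_size, b_reg, b_shr, b_user)) {
    if (!is.numeric(v) || length(v) != 1L || v < 1) {
      abort("all device limits must be single numbers >= 1")
    }
  }
  structure(
    list(sm_num = as.integer(sm_num), t_max = as.integer(t_max),
         b_hw = as.integer(b_hw), warp_size = as.integer(warp_size),
         b_reg = b_reg, b_shr = b_shr, b_user = b_user),
    class = "device_model"
  )
}

#' @export
print.device_model <- function(x, ...) {
  cat(sprintf("<device_model> %d SMs, %d threads/SM, <= %d blocks/SM, warp %d\n",
              x$sm_num, x$t_max, x$b_hw, x$warp_size))
  invisible(x)
}

#' Named device profiles
#'
#' @param name Profile name; `"tesla-c2050"` (14 SMs, 1024 resident threads
#'   per SM, 8 blocks per SM, warp 32) is the bundled default.
#' @return A `device_model`.
#' @export
device_profile <- function(name = "tesla-c2050") {
  profiles <- list(
    "tesla-c2050" = device_model(sm_num = 14L, t_max = 1024L, b_hw = 8L,
                                 warp_size = 32L)
  )
  if (!name %in% names(profiles)) {
    abort(sprintf("unknown device profile '%s'; available: %s", name,
                  paste(names(profiles), collapse = ", ")))
  }
  profiles[[name]]
}

#' SM occupancy
#'
#' The fraction of an SM's resident-thread capacity in use:
#' `(blocks * threads_per_block) / t_max`.
#'
#' @param blocks Active blocks on the SM.
#' @param t_num Threads per block.
#' @param t_max Maximum resident threads per SM.
#' @return Occupancy fraction.
#' @export
#' @examples
#' occupancy(2, 64, 1024)  # 0.125
#' occupancy(8, 64, 1024)  # 0.5
occupancy <- function(blocks, t_num, t_max) {
  if (any(c(blocks, t_num, t_max) <= 0)) abort("all occupancy inputs must be positive")
  (blocks * t_num) / t_max
}

#' Total blocks needed for a thread workload
#'
#' `ceiling(total_threads / t_num)`: the block count launched for a workload
#' of one thread per alignment task.
#'
#' @param total_threads Number of threads (alignment tasks).
#' @param t_num Threads per block.
#' @return Integer block count.
#' @export
#' @examples
#' workload_blocks(1000, 64)   # 16
#' workload_blocks(1000, 512)  # 2
workload_blocks <- function(total_threads, t_num) {
  if (total_threads <= 0 || t_num <= 0) abort("inputs must be positive")
  as.integer(ceiling(total_threads / t_num))
}

#' Effective blocks per SM
#'
#' The number of blocks actually resident on one SM:
#' `min(b_user, b_reg, b_shr, b_hw, ceiling(t_max / t_num))`, further capped
#' by the workload's blocks spread over the SMs
#' (`ceiling(workload_blocks / sm_num)`) when a finite workload is given.
#' Emits a warning when `t_num` is not a multiple of the warp size, since
#' partially filled warps waste scheduling slots.
#'
#' @param device A `device_model`.
#' @param t_num Threads per block.
#' @param workload_blocks Total blocks in the workload, or `Inf` for an
#'   unlimited supply.
#' @return Integer blocks per SM.
#' @export
#' @examples
#' effective_blocks(device_model(), t_num = 64)  # min(ceiling(1024/64), 8) = 8
effective_blocks <- function(device, t_num, workload_blocks = Inf) {
  stopifnot(inherits(device, "device_model"))
  if (t_num < 1) abort("`t_num` must be >= 1")
  if (workload_blocks < 0) abort("`workload_blocks` must be >= 0")
  if (t_num %% device$warp_size != 0) {
    warn(sprintf("threads per block (%d) is not a multiple of the warp size (%d)",
                 as.integer(t_num), device$warp_size))
  }
  b <- min(device$b_user, device$b_reg, device$b_shr, device$b_hw,
           ceiling(device$t_max / t_num))
  if (is.finite(workload_blocks)) {
    b <- min(b, ceiling(workload_blocks / device$sm_num))
  }
  as.integer(b)
}

#' Adaptive tile size
#'
#' The number of subject sequences batched per round so that
#' `tile * n_permutations` alignment tasks saturate the modeled device:
#' `T = floor(sm_num * t_max / N)`. Each round then carries `T * N`
#' alignments (14000 with the default profile and N = 1000).
#'
#' @param device A `device_model`.
#' @param n_permutations Permutations per subject (N).
#' @return Integer tile size `T >= 1`.
#' @export
#' @examples
#' tile_size(device_model(), 1000)  # floor(14 * 1024 / 1000) = 14
tile_size <- function(device, n_permutations) {
  stopifnot(inherits(device, "device_model"))
  if (n_permutations < 1) abort("`n_permutations` must be >= 1")
  t <- floor(device$sm_num * device$t_max / n_permutations)
  if (t < 1) {
    abort(sprintf(
      "infeasible tile: floor(%d * %d / %d) = 0; reduce N or chunk the permutations",
      device$sm_num, device$t_max, as.integer(n_permutations)))
  }
  as.integer(t)
}
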