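#' Published PM2.5 benchmark metrics for six polluted cities
#'
#' Published test-set RMSE, MAE and R-squared values for six forecasting
#' models applied to daily PM2.5 in six heavily polluted Chinese cities
#' (Binzhou, Jinan, Handan, Taiyuan, Xinxiang, Zibo; 2021 test year).
#' These published numbers are inputs for the comparison arithmetic in
#' [comparison_report()] and [percent_reduction()]; the underlying
#' monitoring data are not redistributable, so the package cannot
#' recompute them.
#'
#' @return Tibble with columns `city`, `model`, `rmse`, `mae`, `r2`.  The
#'   models come in decomposition pairs: `SVM`/`CEEMDAN-SVM`,
#'   `PSO-LSTM`/`CEEMDAN-PSO-LSTM`,
#'   `PSO-CNN-LSTM`/`CEEMDAN-PSO-CNNLSTM`.
#' @export
benchmark_city_models <- function() {
  tibble::tribble(
    ~city, ~model, ~rmse, ~mae, ~r2,
    "Binzhou", "SVM", 21.25, 19.86, 0.66,
    "Binzhou", "CEEMDAN-SVM", 18.65, 17.11, 0.73,
    "Binzhou", "PSO-LSTM", 26.94, 18.97, 0.45,
    "Binzhou", "PSO-CNN-LSTM", 26.32, 18.68, 0.47,
    "Binzhou", "CEEMDAN-PSO-LSTM", 17.69, 12.89, 0.76,
    "Binzhou", "CEEMDAN-PSO-CNNLSTM", 12.68, 9.60, 0.86,
    "Jinan", "SVM", 23.13, 21.34, 0.52,
    "Jinan", "CEEMDAN-SVM", 21.52, 19.90, 0.59,
    "Jinan", "PSO-LSTM", 24.28, 16.48, 0.47,
    "Jinan", "PSO-CNN-LSTM", 23.94, 16.47, 0.49,
    "Jinan", "CEEMDAN-PSO-LSTM", 16.04, 11.21, 0.77,
    "Jinan", "CEEMDAN-PSO-CNNLSTM", 11.01, 8.41, 0.87,
    "Handan", "SVM", 23.52, 21.17, 0.67,
    "Handan", "CEEMDAN-SVM", 16.14, 13.20, 0.86,
    "Handan", "PSO-LSTM", 31.48, 21.49, 0.46,
    "Handan", "PSO-CNN-LSTM", 31.16, 21.72, 0.47,
    "Handan", "CEEMDAN-PSO-LSTM", 22.31, 15.10, 0.72,
    "Handan", "CEEMDAN-PSO-CNNLSTM", 12.94, 9.99, 0.88,
    "Taiyuan", "SVM", 23.55, 21.91, 0.62,
    "Taiyuan", "CEEMDAN-SVM", 19.86, 17.92, 0.73,
    "Taiyuan", "PSO-LSTM", 30.79, 20.63, 0.44,
    "Taiyuan", "PSO-CNN-LSTM", 27.31, 18.81, 0.48,
    "Taiyuan", "CEEMDAN-PSO-LSTM", 20.79, 15.16, 0.70,
    "Taiyuan", "CEEMDAN-PSO-CNNLSTM", 12.38, 9.33, 0.88,
    "Xinxiang", "SVM", 23.68, 21.43, 0.53,
    "Xinxiang", "CEEMDAN-SVM", 18.53, 14.85, 0.71,
    "Xinxiang", "PSO-LSTM", 23.91, 17.52, 0.52,
    "Xinxiang", "PSO-CNN-LSTM", 23.29, 18.09, 0.55,
    "Xinxiang", "CEEMDAN-PSO-LSTM", 16.00, 11.53, 0.79,
    "Xinxiang", "CEEMDAN-PSO-CNNLSTM", 11.63, 8.98, 0.88,
    "Zibo", "SVM", 19.95, 18.36, 0.70,
    "Zibo", "CEEMDAN-SVM", 19.70, 17.84, 0.71,
    "Zibo", "PSO-LSTM", 26.89, 18.26, 0.46,
    "Zibo", "PSO-CNN-LSTM", 24.61, 17.00, 0.55,
    "Zibo", "CEEMDAN-PSO-LSTM", 19.77, 14.29, 0.71,
    "Zibo", "CEEMDAN-PSO-CNNLSTM", 10.66, 8.34, 0.89
  )
}

#' Published joint-versus-single PM2.5 forecast metrics
#'
#' Published accuracy of the full hybrid model when the other five
#' pollutants are used as input channels (`joint`) versus a univariate
#' PM2.5-only run (`single`), per city.
#'
#' @return Tibble with columns `city`, `mode` (`joint`/`single`), `rmse`,
#'   `mae`, `r2`.
#' @export
benchmark_joint_single <- function() {
  cities <- c("Binzhou", "Jinan", "Handan", "Taiyuan", "Xinxiang", "Zibo")
  tibble(
    city = rep(cities, each = 2L),
    mode = rep(c("joint", "single"), times = 6L),
    rmse = c(12.68, 14.20, 11.01, 12.23, 12.94, 15.39,
             12.38, 14.44, 11.63, 13.98, 10.66, 14.76),
    mae = c(9.60, 10.40, 8.41, 9.47, 9.99, 11.23,
            9.33, 11.12, 8.98, 10.59, 8.34, 11.09),
    r2 = c(0.86, 0.79, 0.87, 0.84, 0.88, 0.79,
           0.88, 0.83, 0.88, 0.81, 0.89, 0.79)
  )
}

#' Published swarm-tuned hyperparameters per city
#'
#' Published (LSTM cell count, window length) pairs selected by particle
#' swarm search for the six-city PM2.5 benchmark; one shared pair per
#' city.
#'
#' @return Tibble with columns `city`, `cells`, `n`.
#' @export
benchmark_tuned_parameters <- function() {
  tibble(
    city = c("Binzhou", "Jinan", "Handan", "Taiyuan", "Xinxiang", "Zibo"),
    cells = c(92L, 51L, 42L, 93L, 66L, 90L),
    n = c(2L, 4L, 2L, 4L, 2L, 4L)
  )
}
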