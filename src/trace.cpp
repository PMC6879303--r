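#include <Rcpp.h>
using namespace Rcpp;

// Probability assigned to the observed choice on every trial, replaying the
// dataset's own choices and rewards through the model's update equations.
// Model codes follow the R-side registry:
//   1 biased random  2 noisy WSLS  3 RW+softmax  4 choice kernel
//   5 RW+kernel      6 RW+side bias  7 stimulus-blind RL  8 state-based RL
// choices/stimuli are 1-based; block changes re-initialize learner state
// when reset_blocks is true.
static void softmax_inplace(std::vector<double>& drive,
                            std::vector<double>& out) {
  const int K = drive.size();
  double m = drive[0];
  for (int k = 1; k < K; ++k) if (drive[k] > m) m = drive[k];
  double s = 0.0;
  for (int k = 0; k < K; ++k) { out[k] = std::exp(drive[k] - m); s += out[k]; }
  for (int k = 0; k < K; ++k) out[k] /= s;
}

// [[Rcpp::export]]
NumericVector choice_prob_trace_cpp(int model, NumericVector par,
                                    IntegerVector choice,
                                    IntegerVector reward,
                                    IntegerVector stimulus,
                                    IntegerVector block,
                                    int n_choices, int n_stimuli,
                                    double q0, bool reset_blocks) {
  const int T = choice.size();
  const int K = n_choices;
  NumericVector out(T);

  // parameter unpack by model
  double b = 0, eps = 0, alpha = 0, beta = 0, alpha_c = 0, beta_c = 0, bias = 0;
  switch (model) {
    case 1: b = par[0]; break;
    case 2: eps = par[0]; break;
    case 3: alpha = par[0]; beta = par[1]; break;
    case 4: alpha_c = par[0]; beta_c = par[1]; break;
    case 5: alpha = par[0]; beta = par[1]; alpha_c = par[2]; beta_c = par[3];
            break;
    case 6: alpha = par[0]; beta = par[1]; bias = par[2]; break;
    case 7: case 8: alpha = par[0]; beta = par[1]; break;
    default: stop("unknown model code");
  }

  const int nq = (model == 8) ? n_stimuli * K : K;
  std::vector<double> q(nq, q0), ck(K, 0.0), drive(K), p(K);
  int last_choice = -1, last_reward = -1;

  for (int t = 0; t < T; ++t) {
    if (reset_blocks && t > 0 && block[t] != block[t - 1]) {
      std::fill(q.begin(), q.end(), q0);
      std::fill(ck.begin(), ck.end(), 0.0);
      last_choice = -1; last_reward = -1;
    }
    const int c = choice[t] - 1;
    const int s = (model == 7 || model == 8) ? stimulus[t] - 1 : -1;

    double pc;
    switch (model) {
      case 1:
        pc = (c == 0) ? b : 1.0 - b;
        break;
      case 2:
        if (last_choice < 0) {
          pc = 0.5;
        } else {
          int target = (last_reward == 1) ? last_choice : 1 - last_choice;
          pc = (c == target) ? 1.0 - eps / 2.0 : eps / 2.0;
        }
        break;
      case 3: case 7:
        for (int k = 0; k < K; ++k) drive[k] = beta * q[k];
        softmax_inplace(drive, p);
        pc = p[c];
        break;
      case 4:
        for (int k = 0; k < K; ++k) drive[k] = beta_c * ck[k];
        softmax_inplace(drive, p);
        pc = p[c];
        break;
      case 5:
        for (int k = 0; k < K; ++k) drive[k] = beta * q[k] + beta_c * ck[k];
        softmax_inplace(drive, p);
        pc = p[c];
        break;
      case 6:
        drive[0] = beta * (q[0] + bias);
        drive[1] = beta * q[1];
        softmax_inplace(drive, p);
        pc = p[c];
        break;
      case 8:
        for (int k = 0; k < K; ++k) drive[k] = beta * q[s * K + k];
        softmax_inplace(drive, p);
        pc = p[c];
        break;
      default: pc = NA_REAL;
    }
    out[t] = pc;

    // state update
    const double r = reward[t];
    if (model == 3 || model == 5 || model == 6 || model == 7) {
      q[c] += alpha * (r - q[c]);
    } else if (model == 8) {
      q[s * K + c] += alpha * (r - q[s * K + c]);
    }
    if (model == 4 || model == 5) {
      for (int k = 0; k < K; ++k) {
        ck[k] += alpha_c * (((k == c) ? 1.0 : 0.0) - ck[k]);
      }
    }
    last_choice = c; last_reward = (int)r;
  }
  return out;
}
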