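#include <Rcpp.h>
#include <R_ext/Rdynload.h>
using namespace Rcpp;

List forward_select_smo(NumericMatrix X, IntegerVector y01, IntegerVector fold,
                        int n_features, double cost);

RcppExport SEXP _octexture_forward_select_smo(SEXP XSEXP, SEXP ySEXP,
                                              SEXP foldSEXP, SEXP nSEXP,
                                              SEXP cSEXP) {
BEGIN_RCPP
  Rcpp::RObject out;
  Rcpp::RNGScope scope;
  Rcpp::traits::input_parameter<NumericMatrix>::type X(XSEXP);
  Rcpp::traits::input_parameter<IntegerVector>::type y01(ySEXP);
  Rcpp::traits::input_parameter<IntegerVector>::type fold(foldSEXP);
  Rcpp::traits::input_parameter<int>::type n_features(nSEXP);
  Rcpp::traits::input_parameter<double>::type cost(cSEXP);
  out = Rcpp::wrap(forward_select_smo(X, y01, fold, n_features, cost));
  return out;
END_RCPP
}

static const R_CallMethodDef CallEntries[] = {
  {"_octexture_forward_select_smo",
   (DL_FUNC) &_octexture_forward_select_smo, 5},
  {NULL, NULL, 0}
};

RcppExport void R_init_octexture(DllInfo *dll) {
  R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
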