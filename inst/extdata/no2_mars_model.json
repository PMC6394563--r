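{"intercept":76.358,"coefficients":[-16.112,32.65,-8.6937,44.605],"basis":[{"terms":[{"var":1,"sign":1,"knot":-2.3324}]},{"terms":[{"var":2,"sign":-1,"knot":0.55517}]},{"terms":[{"var":2,"sign":-1,"knot":0.55517},{"var":1,"sign":-1,"knot":2.8871}]},{"terms":[{"var":1,"sign":1,"knot":2.8871}]}],"penalty":3,"sse":null,"gcv":null,"n_train":null}
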