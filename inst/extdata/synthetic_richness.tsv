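name	richness
t6	553
t17	27
t50	8
t49	4
t21	5
t20	4
t71	3
t70	3
t78	3
t90	1
t89	4
t12	1219
t48	13
t47	2
t42	25
t43	15
t116	1
t115	1
t61	1
t45	1
t44	126
t24	10
t38	17
t37	429
t23	6
t1	593
t86	1
t85	1
t34	10
t15	159
t7	151
t3	1854
t96	1
t95	2
t16	3
t82	1
t81	1
t102	1
t101	1
t41	6
t40	3
t56	3
t88	1
t87	9
t58	1
t57	2
t108	1
t107	1
t60	16
t59	1
t80	2
t79	1
t94	1
t93	12
t98	1
t97	2
t36	67
t35	6
t13	14
t67	3
t106	1
t105	1
t46	1
t104	1
t103	2
t74	1
t73	12
t112	1
t111	1
t39	4
t30	29
t11	4
t10	1241
t120	1
t119	1
t55	1
t54	8
t118	1
t117	2
t75	1
t28	22
t66	4
t114	1
t113	1
t51	51
t27	1
t26	1285
t18	14136
t72	3
t110	1
t109	1
t77	3
t76	5
t14	4
t53	1
t52	122
t19	48
t33	1
t32	8
t9	56
t8	12
t69	1
t68	5
t100	1
t99	1
t63	1
t62	9
t31	3
t5	79
t29	20
t65	1
t64	9
t22	4
t92	1
t91	2
t84	2
t83	1
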